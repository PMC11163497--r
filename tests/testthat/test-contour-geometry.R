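test_that("contour stacks validate their invariants", {
  sq <- cbind(c(-5, 5, 5, -5), c(-5, -5, 5, 5))
  cs <- contour_stack("brainstem", list(list(z = 4, polygons = list(sq)),
                                        list(z = 0, polygons = list(sq))))
  expect_equal(vapply(cs$slices, `[[`, numeric(1), "z"), c(0, 4))  # sorted
  expect_error(contour_stack("x", list(list(z = 0, polygons = list(sq)),
                                       list(z = 0, polygons = list(sq)))),
               class = "segqa_validation_error")
  expect_error(contour_stack("x", list(list(z = 0, polygons = list(sq[1:2, ])))),
               class = "segqa_validation_error")
  expect_error(structure_pair("p", cs, contour_stack("other", cs$slices)),
               class = "segqa_validation_error")
  expect_error(voxel_grid(c(0, 0, 0), c(1, 0, 2), c(5, 5, 1)),
               class = "segqa_validation_error")
})

test_that("pixel-centre rasterization counts voxels exactly on aligned squares", {
  # 10 mm square with edges on half-integers: 10 x 10 centres inside
  sq <- cbind(c(-5, 5, 5, -5), c(-5, -5, 5, 5)) + 0.5
  g <- voxel_grid(c(-9, -9, 0), c(1, 1, 2), c(20, 20, 1))
  cs <- contour_stack("x", list(list(z = 0, polygons = list(sq))))
  expect_identical(sum(rasterize(cs, g)$voxels), 100L)

  # the same square replicated on 20 slices is additive
  cs20 <- contour_stack("x", lapply(1:20, function(k) {
    list(z = 2 * (k - 1), polygons = list(sq))
  }))
  g20 <- voxel_grid(c(-9, -9, 0), c(1, 1, 2), c(20, 20, 20))
  expect_identical(sum(rasterize(cs20, g20)$voxels), 2000L)
})

test_that("even-odd rule carves holes and matches a brute-force oracle", {
  outer_sq <- cbind(c(-8, 8, 8, -8), c(-8, -8, 8, 8)) + 0.5
  inner_sq <- cbind(c(-5, 5, 5, -5), c(-5, -5, 5, 5)) + 0.5
  g <- voxel_grid(c(-9, -9, 0), c(1, 1, 2), c(20, 20, 1))
  ann <- contour_stack("x", list(list(z = 0, polygons = list(outer_sq, inner_sq))))
  m <- rasterize(ann, g)
  # brute force: per-pixel parity of the two point-in-polygon tests
  xs <- seq(-9, 10); ys <- seq(-9, 10)
  pts <- expand.grid(x = xs, y = ys)
  in_outer <- pracma::inpolygon(pts$x, pts$y, outer_sq[, 1], outer_sq[, 2], boundary = TRUE)
  in_inner <- pracma::inpolygon(pts$x, pts$y, inner_sq[, 1], inner_sq[, 2], boundary = TRUE)
  expect_identical(as.vector(m$voxels[, , 1]), as.vector(xor(in_outer, in_inner)))
  expect_identical(sum(m$voxels), 16L * 16L - 100L)
})

test_that("point-in-polygon agrees with an independent ray-casting oracle", {
  set.seed(42)
  for (rep in 1:5) {
    nv <- sample(5:12, 1)
    ang <- sort(runif(nv, 0, 2 * pi))
    rad <- runif(nv, 2, 10)
    poly <- cbind(rad * cos(ang), rad * sin(ang))
    px <- runif(1000, -11, 11); py <- runif(1000, -11, 11)
    expect_equal(points_in_polygon(px, py, poly),
                 as.logical(pracma::inpolygon(px, py, poly[, 1], poly[, 2],
                                              boundary = TRUE)))
  }
})

test_that("boundary pixel centres count as inside", {
  # square with edges passing exactly through pixel centres: 11 x 11
  sq <- cbind(c(-5, 5, 5, -5), c(-5, -5, 5, 5))
  g <- voxel_grid(c(-9, -9, 0), c(1, 1, 2), c(20, 20, 1))
  m <- rasterize(contour_stack("x", list(list(z = 0, polygons = list(sq)))), g)
  expect_identical(sum(m$voxels), 121L)
  # diagonal edges through centres too
  dia <- cbind(c(-4, 0, 4, 0), c(0, -4, 0, 4))
  md <- rasterize(contour_stack("x", list(list(z = 0, polygons = list(dia)))), g)
  xs <- seq(-9, 10); pts <- expand.grid(x = xs, y = xs)
  expect_identical(sum(md$voxels),
                   sum(pracma::inpolygon(pts$x, pts$y, dia[, 1], dia[, 2],
                                         boundary = TRUE)))
})

test_that("rasterize -> trace -> rasterize is idempotent on the mask", {
  set.seed(7)
  for (arch in c("ellipsoid", "cylinder", "horseshoe")) {
    ph <- make_phantom(arch, radius = 9, n_slices = 4)
    ph <- perturb(ph, "boundary_noise", amplitude = 0.8, seed = 11)
    g <- fit_grid(ph)
    m1 <- rasterize(ph, g)
    m2 <- rasterize(trace_mask(m1, ph$organ), g)
    expect_identical(m1$voxels, m2$voxels)
  }
})

test_that("rasterized volume converges to polygon area times slab thickness", {
  disc <- make_phantom("cylinder", radius = 10, n_slices = 1, n_vertices = 64)
  target <- shoelace_area(disc$slices[[1]]$polygons[[1]]) * 2
  rel_err <- vapply(c(1, 0.5, 0.25), function(h) {
    g <- fit_grid(disc, spacing = c(h, h))
    vol <- sum(rasterize(disc, g)$voxels) * prod(g$spacing)
    abs(vol - target) / target
  }, numeric(1))
  expect_true(all(diff(rel_err) < 0))
  expect_lt(rel_err[3], 0.01)
})

test_that("misaligned slices and out-of-extent polygons are rejected", {
  sq <- cbind(c(-5, 5, 5, -5), c(-5, -5, 5, 5))
  g <- voxel_grid(c(-9, -9, 0), c(1, 1, 2), c(20, 20, 2))
  off_plane <- contour_stack("x", list(list(z = 5, polygons = list(sq))))
  expect_error(rasterize(off_plane, g), class = "segqa_alignment_error")
  big <- contour_stack("x", list(list(z = 0, polygons = list(sq * 4))))
  expect_error(rasterize(big, g), class = "segqa_extent_error")
})
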