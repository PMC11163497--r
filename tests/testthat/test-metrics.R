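make_mask <- function(setter, dim = c(6, 6, 2), origin = c(0, 0, 0)) {
  v <- array(FALSE, dim)
  v <- setter(v)
  binary_mask(voxel_grid(origin, c(1, 1, 2), dim), v)
}

test_that("dsc_3d handles identity, disjoint and partial overlap", {
  a <- make_mask(function(v) { v[1:3, , 1] <- TRUE; v })
  expect_equal(dsc_3d(a, a), 1)
  b <- make_mask(function(v) { v[4:6, , 2] <- TRUE; v })
  expect_equal(dsc_3d(a, b), 0)
  c <- make_mask(function(v) { v[2:4, , 1] <- TRUE; v })
  expect_equal(dsc_3d(a, c), 2 * 12 / (18 + 18))
  expect_equal(dsc_3d(a, c), dsc_3d(c, a))
  empty <- make_mask(identity)
  expect_error(dsc_3d(empty, empty), class = "segqa_undefined_metric_error")
  shifted <- make_mask(function(v) { v[1:3, , 1] <- TRUE; v }, origin = c(5, 0, 0))
  expect_error(dsc_3d(a, shifted), class = "segqa_geometry_error")
})

test_that("dsc_3d is invariant under a rigid shift of the shared frame", {
  cyl <- make_phantom("cylinder", radius = 8, n_slices = 3)
  ell <- make_phantom("ellipsoid", radius = 8, n_slices = 3)
  g0 <- fit_grid(cyl, ell)
  d0 <- dsc_3d(rasterize(cyl, g0), rasterize(ell, g0))
  sh <- c(13, -7)
  cyl2 <- translate_stack(cyl, sh[1], sh[2])
  ell2 <- translate_stack(ell, sh[1], sh[2])
  g1 <- voxel_grid(g0$origin + c(sh, 0), g0$spacing, g0$dim)
  expect_equal(dsc_3d(rasterize(cyl2, g1), rasterize(ell2, g1)), d0)
})

test_that("dsc_3d strictly decreases with growing in-plane offset", {
  cyl <- make_phantom("cylinder", radius = 5, n_slices = 2)
  dscs <- vapply(c(0, 2, 4, 6), function(off) {
    moved <- translate_stack(cyl, off, 0)
    g <- fit_grid(cyl, moved, spacing = c(0.5, 0.5))
    dsc_3d(rasterize(cyl, g), rasterize(moved, g))
  }, numeric(1))
  expect_equal(dscs[1], 1)
  expect_true(all(diff(dscs) < 0))
})

test_that("truncated cylinders follow the closed-form DSC with zero HD95", {
  # identical cross-sections cancel in the Dice ratio, so removing k of N
  # slices gives exactly 2(N-k)/(2N-k) while every shared slice is identical
  cyl <- make_phantom("cylinder", radius = 10, n_slices = 20)
  cut <- perturb(cyl, "truncate_si", k = 5)
  g <- fit_grid(cyl, cut)
  expect_equal(dsc_3d(rasterize(cyl, g), rasterize(cut, g)), 6 / 7)
  hd <- hd95_2d(cyl, cut)
  expect_equal(hd$hd95, 0, tolerance = 1e-9)
  expect_identical(hd$n_shared, 15L)
  expect_identical(hd$n_gold_only, 5L)
})

test_that("hd95_2d: identical stacks give zero; pure translation is bounded", {
  ph <- perturb(make_phantom("ellipsoid", radius = 12, n_slices = 4),
                "boundary_noise", amplitude = 0.6, seed = 5)
  expect_equal(hd95_2d(ph, ph)$hd95, 0, tolerance = 1e-12)

  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  a <- contour_stack("x", list(list(z = 0, polygons = list(sq))))
  b <- translate_stack(a, 3, 0)
  h <- hd95_2d(a, b, sampling_step = 0.25)
  expect_lte(h$hd95, 3)
  # max pooled distance is exactly the offset: use the 100th percentile
  expect_equal(hd95_2d(a, b, sampling_step = 0.25, probs = 1)$hd95, 3)
})

test_that("hd95_2d matches the brute-force all-pairs oracle", {
  set.seed(31)
  for (rep in 1:4) {
    gold <- perturb(make_phantom("ellipsoid", radius = 6, n_slices = 2,
                                 n_vertices = 12),
                    "boundary_noise", amplitude = 0.5, seed = rep)
    auto <- perturb(gold, "boundary_noise", amplitude = 1, seed = rep + 100)
    h <- hd95_2d(gold, auto, sampling_step = 2)
    expect_equal(h$hd95, brute_hd95(gold, auto, sampling_step = 2),
                 tolerance = 1e-9)
  }
  # multi-polygon slices too
  gold <- make_phantom("horseshoe", radius = 8, n_slices = 1, n_vertices = 16)
  auto <- perturb(gold, "attach_component", blob_radius = 2,
                  blob_slices = 1)
  expect_equal(hd95_2d(gold, auto, sampling_step = 2)$hd95,
               brute_hd95(gold, auto, sampling_step = 2), tolerance = 1e-9)
})

test_that("slices present in only one stack are excluded and counted", {
  cyl <- make_phantom("cylinder", radius = 8, n_slices = 6)
  cut <- perturb(cyl, "truncate_si", k = 6 - 1, end = "inferior")
  h <- hd95_2d(cyl, cut)
  expect_identical(h$n_shared, 1L)
  expect_identical(h$n_gold_only, 5L)
  expect_identical(h$n_auto_only, 0L)
  # disjoint z ranges: metric undefined, not zero
  far <- contour_stack("cylinder", lapply(cyl$slices, function(s) {
    s$z <- s$z + 100; s
  }))
  h2 <- hd95_2d(cyl, far)
  expect_true(is.na(h2$hd95))
  expect_identical(h2$n_shared, 0L)
  expect_error(hd95_2d(cyl, contour_stack("cylinder", list())),
               class = "segqa_undefined_metric_error")
})

test_that("compare_pair assembles the full metric row and CSV round-trips", {
  gold <- make_phantom("cylinder", radius = 10, n_slices = 8)
  auto <- perturb(gold, "truncate_si", k = 2)
  row <- compare_pair(structure_pair("p7", gold, auto))
  expect_equal(row$dsc, 2 * 6 / (8 + 6), tolerance = 1e-12)
  expect_equal(row$hd95_2d, 0, tolerance = 1e-9)
  expect_identical(row$n_shared_slices, 6L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(row, f)
  back <- read_metrics_csv(f)
  expect_equal(back$dsc, row$dsc)
  expect_identical(back$patient_id, "p7")
})
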