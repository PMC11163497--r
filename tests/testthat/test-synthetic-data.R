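test_that("phantom geometry matches its closed forms and is deterministic", {
  cyl <- make_phantom("cylinder", radius = 10, n_slices = 20, n_vertices = 64)
  expect_length(cyl$slices, 20)
  # regular n-gon area: pi r^2 * (n / 2pi) * sin(2pi / n), within 1% of pi r^2
  areas <- vapply(cyl$slices, function(s) shoelace_area(s$polygons[[1]]),
                  numeric(1))
  expect_equal(areas, rep(areas[1], 20))
  expect_lt(abs(areas[1] - pi * 100) / (pi * 100), 0.01)
  expect_equal(areas[1], 100 * (64 / 2) * sin(2 * pi / 64))

  # ellipsoid: radius profile follows a * sqrt(1 - (z/c)^2); widest at equator
  ell <- make_phantom("ellipsoid", radius = 15, n_slices = 15, semi_z = 20)
  radii <- vapply(ell$slices, function(s) {
    max(sqrt(rowSums(s$polygons[[1]]^2)))
  }, numeric(1))
  z <- vapply(ell$slices, `[[`, numeric(1), "z")
  expect_equal(radii, 15 * sqrt(pmax(0, 1 - (z / 20)^2)), tolerance = 1e-9)
  expect_equal(radii[8], 15)  # equatorial slice radius equals the semi-axis

  expect_identical(make_phantom("horseshoe", radius = 40, n_slices = 5),
                   make_phantom("horseshoe", radius = 40, n_slices = 5))
})

test_that("perturbations implement the failure archetypes", {
  cyl <- make_phantom("cylinder", radius = 10, n_slices = 20)

  # superior-inferior truncation: closed-form DSC drop, HD95 blind
  for (k in c(3, 5, 10)) {
    cut <- perturb(cyl, "truncate_si", k = k)
    expect_length(cut$slices, 20 - k)
    g <- fit_grid(cyl, cut)
    expect_equal(dsc_3d(rasterize(cyl, g), rasterize(cut, g)),
                 2 * (20 - k) / (40 - k))
    expect_equal(hd95_2d(cyl, cut)$hd95, 0, tolerance = 1e-9)
  }
  expect_error(perturb(cyl, "truncate_si", k = 20),
               class = "segqa_degenerate_structure_error")

  # zero-degree roll is the identity
  expect_equal(perturb(cyl, "roll", angle = 0), cyl, tolerance = 1e-12)
  # a roll about a distant pivot moves every vertex by ~ 2 sin(a/2) * arm
  rolled <- perturb(cyl, "roll", angle = 7, pivot = c(0, -40))
  v0 <- cyl$slices[[1]]$polygons[[1]]
  v1 <- rolled$slices[[1]]$polygons[[1]]
  shift <- sqrt(rowSums((v1 - v0)^2))
  arm <- sqrt(rowSums(sweep(v0, 2, c(0, -40))^2))
  expect_equal(shift, 2 * sin(7 / 2 * pi / 180) * arm, tolerance = 1e-9)

  # attached component: disjoint second polygon, DSC < 1, same z extent
  att <- perturb(cyl, "attach_component")
  n_polys <- vapply(att$slices, function(s) length(s$polygons), integer(1))
  expect_true(any(n_polys == 2))
  g <- fit_grid(cyl, att)
  expect_lt(dsc_3d(rasterize(cyl, g), rasterize(att, g)), 1)
  expect_identical(range(vapply(att$slices, `[[`, numeric(1), "z")),
                   range(vapply(cyl$slices, `[[`, numeric(1), "z")))

  # boundary noise: reproducible per seed, different across seeds
  n1 <- perturb(cyl, "boundary_noise", amplitude = 0.5, seed = 4)
  n2 <- perturb(cyl, "boundary_noise", amplitude = 0.5, seed = 4)
  n3 <- perturb(cyl, "boundary_noise", amplitude = 0.5, seed = 5)
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
})

test_that("metric-level cohorts follow the truncated-normal failure mixture", {
  # no injected failures: none labeled
  c0 <- simulate_metric_cohort(n_patients = 200, gross_failure_prob = 0, seed = 2)
  expect_false(any(c0$is_failure))
  expect_identical(nrow(c0), 800L)  # 4 default organs
  expect_true(all(c0$dsc > 0 & c0$dsc <= 1))

  # in-control fraction below the three-sigma limit matches the analytic tail
  cb <- simulate_metric_cohort(
    params = data.frame(organ = "brainstem", dsc_mean = 0.81, dsc_sd = 0.06),
    n_patients = 2e5, gross_failure_prob = 0, seed = 3)
  frac <- mean(cb$dsc < 0.63)
  tail <- trunc_normal_tail(0.63, 0.81, 0.06)
  expect_lt(abs(frac - tail), 4 * sqrt(tail * (1 - tail) / 2e5))

  # injected failures land in the failure range and are always detectable
  # against the default limits (recall 1 at range (0.1, 0.4))
  c1 <- simulate_metric_cohort(n_patients = 2000, gross_failure_prob = 0.012,
                               seed = 4)
  fit <- with(oar_reference_defaults(),
              reference_limits(organ, dsc_mean, dsc_sd))
  fl <- predict(fit, c1)
  expect_gt(sum(c1$is_failure), 0)
  recall <- mean(fl$dsc_failed[c1$is_failure])
  expect_gte(recall, 0.99)
  expect_true(all(c1$dsc[c1$is_failure] >= 0.1 & c1$dsc[c1$is_failure] <= 0.4))

  # deterministic per seed
  expect_identical(c1, simulate_metric_cohort(n_patients = 2000,
                                              gross_failure_prob = 0.012,
                                              seed = 4))
  expect_error(simulate_metric_cohort(failure_dsc_range = c(0.1, 0.9)),
               class = "segqa_validation_error")
})

test_that("contour cohorts are reproducible with a faithful manifest", {
  coh <- simulate_contour_cohort(6, organs = c("brainstem", "mandible"),
                                 failure_prob = 0.5, seed = 99)
  coh2 <- simulate_contour_cohort(6, organs = c("brainstem", "mandible"),
                                  failure_prob = 0.5, seed = 99)
  expect_identical(coh$manifest, coh2$manifest)
  expect_identical(length(coh$pairs), nrow(coh$manifest))
  # truncated pairs really have fewer auto slices; rolled pairs same count
  for (i in seq_along(coh$pairs)) {
    p <- coh$pairs[[i]]
    inj <- coh$manifest$injected[i]
    if (inj == "truncate_si") {
      expect_lt(length(p$auto$slices), length(p$gold$slices))
    } else {
      expect_identical(length(p$auto$slices), length(p$gold$slices))
    }
    if (inj == "attach_component") {
      expect_true(any(vapply(p$auto$slices, function(s) length(s$polygons),
                             integer(1)) > 1))
    }
  }
})

test_that("manifest-derived annotations map archetypes to review verdicts", {
  man <- data.frame(patient_id = c("a", "b", "c", "d"),
                    organ = "brainstem",
                    injected = c("roll", "attach_component", "truncate_si", "none"),
                    stringsAsFactors = FALSE)
  ann <- annotations_from_manifest(man)
  expect_identical(ann$verdict, c("setup", "anatomy", "artefacts"))
  # with flags: unexplained flags get 'unknown', unflagged injections drop out
  flags <- data.frame(patient_id = c("a", "d"), organ = "brainstem",
                      dsc_failed = TRUE)
  ann2 <- annotations_from_manifest(man, flags)
  expect_setequal(ann2$patient_id, c("a", "d"))
  expect_identical(ann2$verdict[ann2$patient_id == "d"], "unknown")
})
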