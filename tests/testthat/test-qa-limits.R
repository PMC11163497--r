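# build a sample with an exact mean and sample SD
sample_with_moments <- function(n, mean, sd) {
  x <- seq_len(n)
  x <- (x - mean(x)) / stats::sd(x)
  x * sd + mean
}

test_that("three-sigma limits follow mean - 3 * SD with sample SD", {
  x <- sample_with_moments(50, 0.81, 0.06)
  fit <- fit_reference_limits(x, organ = "brainstem")
  lim <- fit$limits
  expect_equal(lim$dsc_mean, 0.81)
  expect_equal(lim$dsc_sd, 0.06)
  expect_equal(lim$dsc_lower_limit, 0.81 - 3 * 0.06)
  expect_identical(lim$n_reference, 50L)

  y <- sample_with_moments(50, 0.91, 0.02)
  expect_equal(fit_reference_limits(y, organ = "mandible")$limits$dsc_lower_limit,
               0.85)

  # zero variance: limit equals the mean
  z <- rep(0.9, 10)
  expect_equal(fit_reference_limits(z, organ = "x")$limits$dsc_lower_limit, 0.9)

  # lower limit clamps at zero
  w <- sample_with_moments(20, 0.2, 0.1)
  expect_equal(fit_reference_limits(w, organ = "x")$limits$dsc_lower_limit, 0)
})

test_that("limit fitting validates its inputs", {
  expect_error(fit_reference_limits(0.8, organ = "x"),
               class = "segqa_insufficient_data_error")
  expect_error(fit_reference_limits(c(0.5, 1.2), organ = "x"),
               class = "segqa_domain_error")
  expect_error(fit_reference_limits(c(0.5, 0.6)),  # organ missing
               class = "segqa_validation_error")
})

test_that("HD limits are fitted as mean + 3 * SD when values are supplied", {
  dsc <- sample_with_moments(50, 0.81, 0.06)
  hd <- sample_with_moments(50, 5, 2.2)
  fit <- fit_reference_limits(dsc, organ = "brainstem", hd = hd)
  expect_equal(fit$limits$hd_upper_limit, 5 + 3 * 2.2)
})

test_that("flagging is strict at the limit and keeps undefined HD as NA", {
  # mean/SD chosen binary-exact so the limit is exactly representable
  fit <- reference_limits("brainstem", dsc_mean = 0.75, dsc_sd = 0.0625,
                          hd_mean = 5, hd_sd = 2.2)
  expect_identical(fit$limits$dsc_lower_limit, 0.5625)
  res <- data.frame(
    patient_id = c("a", "b", "c", "d"), organ = "brainstem",
    dsc = c(0.5625, 0.5624, 0.40, 0.80),
    hd95_2d = c(3, 13.7, NA, 7.6))
  fl <- predict(fit, res)
  expect_identical(fl$dsc_failed, c(FALSE, TRUE, TRUE, FALSE))
  # hd limit is 5 + 6.6 = 11.6: 13.7 fails, 7.6 and 3 do not, NA stays NA
  expect_identical(fl$hd_failed, c(FALSE, TRUE, NA, FALSE))
  expect_error(predict(fit, data.frame(organ = "mandible", dsc = 0.9)),
               class = "segqa_routing_error")
  # idempotent and deterministic
  expect_identical(predict(fit, res), fl)
  expect_identical(flag_gross_failures(res, fit), fl)
})

test_that("flagged fraction of an in-control cohort matches the 3-sigma tail", {
  mu <- 0.81; s <- 0.06
  fit <- reference_limits("brainstem", dsc_mean = mu, dsc_sd = s)
  coh <- simulate_metric_cohort(
    params = data.frame(organ = "brainstem", dsc_mean = mu, dsc_sd = s),
    n_patients = 2e5, gross_failure_prob = 0, seed = 1234)
  frac <- mean(predict(fit, coh)$dsc_failed)
  tail <- trunc_normal_tail(mu - 3 * s, mu, s)
  mc_se <- sqrt(tail * (1 - tail) / 2e5)
  expect_lt(abs(frac - tail), 4 * mc_se)
})

test_that("the 50-draw limit estimator has its theoretical precision", {
  # SD of (mean - 3*sd) at n = 50 is sigma * sqrt(1/n + 9/(2(n-1))) ~ 0.334 sigma,
  # so about 87% of estimates fall within half a sigma of the truth
  mu <- 0.81; s <- 0.06
  n_rep <- 400
  est <- vapply(seq_len(n_rep), function(r) {
    x <- simulate_metric_cohort(
      params = data.frame(organ = "o", dsc_mean = mu, dsc_sd = s),
      n_patients = 50, gross_failure_prob = 0, seed = 5000 + r)$dsc
    mean(x) - 3 * sd(x)
  }, numeric(1))
  err <- est - (mu - 3 * s)
  theo_sd <- s * sqrt(1 / 50 + 9 / (2 * 49))
  expect_lt(abs(sd(err) / theo_sd - 1), 0.15)
  cover <- mean(abs(err) < 0.5 * s)
  expect_gt(cover, 0.80)
  expect_lt(cover, 0.93)
})

test_that("ref_limits methods print, coerce and simulate coherently", {
  fit <- reference_limits(c("brainstem", "mandible"),
                          dsc_mean = c(0.81, 0.91), dsc_sd = c(0.06, 0.02),
                          n_reference = 50)
  expect_output(print(fit), "brainstem")
  expect_output(print(summary(fit)), "gross failure")
  cf <- coef(fit)
  expect_equal(cf["mandible", "dsc_lower_limit"], 0.85)
  sim <- simulate(fit, nsim = 500, seed = 77)
  expect_identical(nrow(sim), 1000L)
  expect_true(all(sim$dsc > 0 & sim$dsc <= 1))
  sim2 <- simulate(fit, nsim = 500, seed = 77)
  expect_identical(sim, sim2)
  # plot method runs silently to a null device
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  flags <- plot(fit, metrics = sim)
  expect_s3_class(flags, "qa_flags")
})

test_that("limits CSV round-trips through read_limits_csv", {
  fit <- reference_limits(c("brainstem", "parotid_r"),
                          dsc_mean = c(0.81, 0.74), dsc_sd = c(0.06, 0.08),
                          n_reference = 50)
  f <- withr::local_tempfile(fileext = ".csv")
  write_limits_csv(fit, f)
  back <- read_limits_csv(f)
  expect_s3_class(back, "ref_limits")
  expect_equal(back$limits$dsc_lower_limit, fit$limits$dsc_lower_limit)
  res <- data.frame(organ = "parotid_r", dsc = 0.3)
  expect_true(predict(back, res)$dsc_failed)
})
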