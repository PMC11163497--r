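# the published four-organ audit counts used as a worked example throughout
audit_counts <- function() {
  list(organ = c("brainstem", "mandible", "parotid_l", "parotid_r"),
       n_flagged = c(4, 20, 13, 7), n_censored = c(2, 9, 6, 3),
       setup = c(2, 0, 0, 1), anatomy = c(0, 8, 5, 2),
       artefacts = c(0, 3, 0, 1), unknown = c(0, 0, 2, 0))
}

test_that("count-based summary reproduces true failures and rates", {
  cs <- do.call(cohort_summary_from_counts, c(audit_counts(), n_evaluated = 500))
  expect_identical(cs$per_organ$n_true_failures, c(2L, 11L, 7L, 4L))
  expect_equal(100 * cs$per_organ$true_failure_rate, c(0.4, 2.2, 1.4, 0.8))
  expect_identical(cs$pooled$total_true_failures, 24L)
  expect_equal(100 * cs$pooled$overall_rate, 1.2)
  expect_equal(round_half_up(100 * cs$pooled$censored_fraction_of_flagged, 1), 45.5)
})

test_that("record-based summary agrees with counts and is permutation-invariant", {
  set.seed(1)
  recs <- data.frame(
    patient_id = sprintf("p%03d", 1:60), organ = rep(c("a", "b"), each = 30),
    dsc = 0.9, dsc_failed = FALSE, status = "not_failed",
    category = NA_character_, stringsAsFactors = FALSE)
  fail_idx <- c(1:5, 31:34)
  recs$status[fail_idx] <- c("censored", "true_failure", "true_failure",
                             "censored", "true_failure",
                             "true_failure", "censored", "true_failure",
                             "true_failure")
  recs$category[recs$status == "true_failure"] <-
    c("setup", "anatomy", "anatomy", "artefacts", "unknown", "anatomy")
  recs$dsc_failed[fail_idx] <- TRUE
  s1 <- summarize_cohort(recs, n_evaluated = 30)
  expect_identical(s1$per_organ$n_flagged, c(5L, 4L))
  expect_identical(s1$per_organ$n_censored, c(2L, 1L))
  expect_identical(s1$per_organ$n_true_failures, c(3L, 3L))
  expect_equal(s1$per_organ$setup + s1$per_organ$anatomy +
                 s1$per_organ$artefacts + s1$per_organ$unknown,
               s1$per_organ$n_true_failures)
  s2 <- summarize_cohort(recs[sample(nrow(recs)), ], n_evaluated = 30,
                         organs = c("a", "b"))
  expect_equal(s1$per_organ, s2$per_organ)

  expect_error(summarize_cohort(recs, n_evaluated = 3),
               class = "segqa_consistency_error")
  expect_error(summarize_cohort(recs, organs = "a"),
               class = "segqa_routing_error")
})

test_that("empty cohorts yield zero rates and an undefined censored fraction", {
  recs <- data.frame(patient_id = "p1", organ = "a", dsc = 0.9,
                     dsc_failed = FALSE, status = "not_failed",
                     category = NA_character_)
  cs <- summarize_cohort(recs, n_evaluated = 10)
  expect_identical(cs$per_organ$n_true_failures, 0L)
  expect_equal(cs$pooled$overall_rate, 0)
  expect_true(is.na(cs$pooled$censored_fraction_of_flagged))
  expect_output(print(cs), "n/a")
})

test_that("the report renders the conventional 8-row layout with percent rates", {
  cs <- do.call(cohort_summary_from_counts, c(audit_counts(), n_evaluated = 500))
  rep <- format_report(cs)
  expect_identical(nrow(rep), 8L)
  expect_identical(ncol(rep), 5L)  # label column + 4 organs
  expect_identical(rep$row[1], "Failures")
  expect_identical(rep$row[8], "True failure rate")
  expect_identical(rep$brainstem[8], "0.4%")
  expect_identical(rep$mandible[8], "2.2%")
  expect_identical(rep$parotid_l[7], "7")
})

test_that("rates round half-up at one decimal place", {
  expect_equal(round_half_up(0.45, 1), 0.5)
  expect_equal(round_half_up(45.45, 1), 45.5)  # 20/44 censored fraction
  expect_equal(round_half_up(-0.45, 1), -0.5)
  expect_identical(segqa:::format_percent(0.004), "0.4%")
  expect_identical(segqa:::format_percent(20 / 44), "45.5%")
})

test_that("written reports round-trip into identical summaries", {
  cs <- do.call(cohort_summary_from_counts, c(audit_counts(), n_evaluated = 500))
  dir <- withr::local_tempdir()
  paths <- write_report(cs, dir)
  expect_true(all(file.exists(paths)))
  back <- read_cohort_summary_csv(paths["counts"])
  expect_equal(back$per_organ, cs$per_organ)
  expect_equal(back$pooled, cs$pooled)
})

test_that("plot data carries one (index, dsc, limit) row per comparison", {
  fit <- reference_limits("brainstem", dsc_mean = 0.81, dsc_sd = 0.06)
  res <- data.frame(patient_id = c("a", "b", "c"), organ = "brainstem",
                    dsc = c(0.9, 0.5, 0.7))
  pd <- plot_data(predict(fit, res))
  expect_identical(nrow(pd), 3L)
  expect_identical(pd$patient_index, 1:3)
  expect_identical(pd$dsc_failed, c(FALSE, TRUE, FALSE))
  expect_equal(unique(pd$dsc_lower_limit), 0.63)
})
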