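#' Summarize an audited cohort into per-organ failure rates
#'
#' Aggregates reviewed failure records into the audit summary: per organ the
#' number of flagged comparisons, censored flags (suboptimal manual
#' contour), true failures broken down by mode, and the true-failure rate
#' over the number of evaluated structures; pooled over organs the total
#' true failures, overall rate, and the censored fraction of all flags.
#' Censoring removes a record from the true-failure numerator but not from
#' the evaluated denominator.
#'
#' @param records Failure records from [apply_review()].
#' @param n_evaluated Evaluations per organ: a single count applying to
#'   every organ (e.g. 500) or a named vector by organ. Defaults to the
#'   number of records per organ. Must be at least the flagged count.
#' @param organs Optional organ ordering for the summary (default: order of
#'   appearance).
#' @return An object of class `cohort_summary`: list with `per_organ` (data
#'   frame: `organ`, `n_evaluated`, `n_flagged`, `n_censored`, `setup`,
#'   `anatomy`, `artefacts`, `unknown`, `n_true_failures`,
#'   `true_failure_rate`) and `pooled` (list: `n_evaluated`, `n_flagged`,
#'   `total_true_failures`, `overall_rate`, `censored_fraction_of_flagged`
#'   — `NA` when nothing was flagged).
#' @export
summarize_cohort <- function(records, n_evaluated = NULL, organs = NULL) {
  if (!all(c("organ", "status") %in% names(records))) {
    stop_segqa("'records' needs columns organ and status", "segqa_validation_error")
  }
  if (is.null(organs)) organs <- unique(records$organ)
  unknown_org <- setdiff(unique(records$organ), organs)
  if (length(unknown_org)) {
    stop_segqa(paste("records reference unknown organ(s):",
                     paste(unknown_org, collapse = ", ")), "segqa_routing_error")
  }
  rows <- lapply(organs, function(org) {
    d <- records[records$organ == org, , drop = FALSE]
    n_flag <- sum(d$status != "not_failed")
    n_cens <- sum(d$status == "censored")
    cats <- vapply(failure_categories(), function(cg) {
      sum(d$status == "true_failure" & d$category == cg, na.rm = TRUE)
    }, integer(1))
    n_eval <- if (is.null(n_evaluated)) nrow(d)
              else if (length(n_evaluated) == 1L && is.null(names(n_evaluated))) n_evaluated
              else n_evaluated[[org]]
    if (is.null(n_eval) || is.na(n_eval) || n_eval < n_flag) {
      stop_segqa(sprintf("organ '%s': n_evaluated (%s) below flagged count (%d)",
                         org, as.character(n_eval), n_flag), "segqa_consistency_error")
    }
    n_true <- n_flag - n_cens
    cbind(data.frame(organ = org, n_evaluated = as.integer(n_eval),
                     n_flagged = n_flag, n_censored = n_cens),
          as.data.frame(as.list(cats)),
          data.frame(n_true_failures = n_true,
                     true_failure_rate = n_true / n_eval))
  })
  per_organ <- do.call(rbind, rows)
  rownames(per_organ) <- NULL
  tot_true <- sum(per_organ$n_true_failures)
  tot_eval <- sum(per_organ$n_evaluated)
  tot_flag <- sum(per_organ$n_flagged)
  pooled <- list(
    n_evaluated = tot_eval,
    n_flagged = tot_flag,
    total_true_failures = tot_true,
    overall_rate = if (tot_eval > 0) tot_true / tot_eval else NA_real_,
    censored_fraction_of_flagged =
      if (tot_flag > 0) sum(per_organ$n_censored) / tot_flag else NA_real_)
  structure(list(per_organ = per_organ, pooled = pooled), class = "cohort_summary")
}

#' Build a cohort summary directly from counts
#'
#' Convenience constructor when only the review bookkeeping (flagged,
#' censored and per-mode counts per organ) is available rather than
#' record-level data — e.g. when reproducing a published audit table.
#'
#' @param organ Character vector of organ labels.
#' @param n_flagged,n_censored Integer vectors per organ.
#' @param setup,anatomy,artefacts,unknown True-failure counts per mode.
#' @param n_evaluated Evaluations per organ (scalar or vector).
#' @return A `cohort_summary` (see [summarize_cohort()]).
#' @export
#' @examples
#' cohort_summary_from_counts(
#'   organ = c("brainstem", "mandible", "parotid_l", "parotid_r"),
#'   n_flagged = c(4, 20, 13, 7), n_censored = c(2, 9, 6, 3),
#'   setup = c(2, 0, 0, 1), anatomy = c(0, 8, 5, 2),
#'   artefacts = c(0, 3, 0, 1), unknown = c(0, 0, 2, 0),
#'   n_evaluated = 500)
cohort_summary_from_counts <- function(organ, n_flagged, n_censored,
                                       setup, anatomy, artefacts, unknown,
                                       n_evaluated) {
  n <- length(organ)
  n_evaluated <- rep_len(as.integer(n_evaluated), n)
  n_flagged <- as.integer(n_flagged); n_censored <- as.integer(n_censored)
  n_true <- n_flagged - n_censored
  if (any(n_censored + setup + anatomy + artefacts + unknown != n_flagged)) {
    stop_segqa("censored + category counts must equal flagged count per organ",
               "segqa_consistency_error")
  }
  if (any(n_evaluated < n_flagged)) {
    stop_segqa("n_evaluated below flagged count", "segqa_consistency_error")
  }
  per_organ <- data.frame(
    organ = organ, n_evaluated = as.integer(n_evaluated),
    n_flagged = as.integer(n_flagged), n_censored = as.integer(n_censored),
    setup = as.integer(setup), anatomy = as.integer(anatomy),
    artefacts = as.integer(artefacts), unknown = as.integer(unknown),
    n_true_failures = as.integer(n_true),
    true_failure_rate = n_true / n_evaluated, stringsAsFactors = FALSE)
  tot_true <- sum(n_true); tot_eval <- sum(n_evaluated); tot_flag <- sum(n_flagged)
  pooled <- list(
    n_evaluated = tot_eval, n_flagged = tot_flag,
    total_true_failures = tot_true,
    overall_rate = if (tot_eval > 0) tot_true / tot_eval else NA_real_,
    censored_fraction_of_flagged =
      if (tot_flag > 0) sum(n_censored) / tot_flag else NA_real_)
  structure(list(per_organ = per_organ, pooled = pooled), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Auto-segmentation audit summary\n\n")
  print(format_report(x), row.names = FALSE)
  p <- x$pooled
  cat(sprintf("\nOverall: %d true failure(s) / %d evaluated = %s; censored fraction of flagged: %s\n",
              p$total_true_failures, p$n_evaluated,
              format_percent(p$overall_rate),
              format_percent(p$censored_fraction_of_flagged)))
  invisible(x)
}

format_percent <- function(x, digits = 1) {
  ifelse(is.na(x), "n/a", paste0(formatC(round_half_up(100 * x, digits),
                                         format = "f", digits = digits), "%"))
}

#' Render a cohort summary as a report table
#'
#' Produces the audit report in its conventional layout: one column per
#' organ and one row each for flagged failures, censored results, the four
#' failure modes, true failures, and the true-failure rate (percent, one
#' decimal place, ties rounded up).
#'
#' @param summary A `cohort_summary`.
#' @return Data frame with a `row` label column and one column per organ.
#' @export
format_report <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"))
  po <- summary$per_organ
  rows <- c("Failures", "Censored (sub-optimal manual contour)",
            "Setup position", "Anatomical", "Image artefacts", "Unknown",
            "True failures", "True failure rate")
  out <- data.frame(row = rows, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(po))) {
    out[[po$organ[i]]] <- c(po$n_flagged[i], po$n_censored[i], po$setup[i],
                            po$anatomy[i], po$artefacts[i], po$unknown[i],
                            po$n_true_failures[i],
                            format_percent(po$true_failure_rate[i]))
  }
  out
}

#' Write a cohort summary to files
#'
#' Writes the report table ([format_report()]) as CSV, the per-organ counts
#' as CSV (machine-readable, round-trippable with
#' [read_cohort_summary_csv()]), and the pooled statistics as JSON.
#'
#' @param summary A `cohort_summary`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(summary, dir, prefix = "audit") {
  stopifnot(inherits(summary, "cohort_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    report = file.path(dir, paste0(prefix, "_report.csv")),
    counts = file.path(dir, paste0(prefix, "_counts.csv")),
    pooled = file.path(dir, paste0(prefix, "_pooled.json")))
  utils::write.csv(format_report(summary), paths["report"], row.names = FALSE)
  utils::write.csv(summary$per_organ, paths["counts"], row.names = FALSE)
  jsonlite::write_json(summary$pooled, paths["pooled"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' @rdname write_report
#' @param path Path to a `*_counts.csv` written by [write_report()].
#' @export
read_cohort_summary_csv <- function(path) {
  po <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(organ = "character"))
  cohort_summary_from_counts(po$organ, po$n_flagged, po$n_censored,
                             po$setup, po$anatomy, po$artefacts, po$unknown,
                             po$n_evaluated)
}

#' Per-organ control-chart plot data
#'
#' Emits, per organ, the (patient index, DSC, lower limit) triples backing
#' the audit control charts (see [plot.ref_limits()]).
#'
#' @param flags Flagged metric results from [predict.ref_limits()].
#' @return Data frame with columns `organ`, `patient_index`, `patient_id`,
#'   `dsc`, `dsc_lower_limit`, `dsc_failed`.
#' @export
plot_data <- function(flags) {
  stopifnot(all(c("organ", "dsc", "dsc_lower_limit") %in% names(flags)))
  out <- do.call(rbind, lapply(split(as.data.frame(flags), flags$organ), function(d) {
    data.frame(organ = d$organ, patient_index = seq_len(nrow(d)),
               patient_id = if ("patient_id" %in% names(d)) d$patient_id else NA,
               dsc = d$dsc, dsc_lower_limit = d$dsc_lower_limit,
               dsc_failed = d$dsc_failed, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
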