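#' Fit per-organ three-sigma gross-failure limits
#'
#' Estimates, per organ, the expected Dice coefficient and its spread from a
#' reference cohort of gold-vs-auto comparisons, and derives the gross-failure
#' action limits of the QA procedure: a structure is flagged when its DSC
#' falls below `mean - 3 * SD` (the lower three-sigma limit, clamped at 0);
#' when 2D 95% Hausdorff distances are available an upper limit
#' `mean + 3 * SD` is fitted for them as well. Under approximate normality
#' about 99.7% of in-control results lie within three sigma, so roughly
#' 0.135% of normal structures are expected below the lower DSC limit.
#'
#' @param data Data frame of reference-cohort metric results with columns
#'   `organ` and `dsc`, optionally `hd95_2d` (as produced by
#'   [compare_pair()]); alternatively a numeric vector of DSC values for a
#'   single organ given in `organ`.
#' @param organ Organ label, only when `data` is a numeric vector.
#' @param hd Optional numeric vector of HD95 values, only when `data` is a
#'   numeric vector.
#' @return An object of class `ref_limits`: a list with element `limits`, a
#'   data frame with one row per organ and columns `organ`, `dsc_mean`,
#'   `dsc_sd`, `dsc_lower_limit`, `hd_mean`, `hd_sd`, `hd_upper_limit`,
#'   `n_reference`.
#' @details The SD is the sample standard deviation (n - 1 denominator).
#'   At least 2 finite DSC values per organ are required and all must lie in
#'   `[0, 1]`. Limits are carried at full precision; round only for display.
#' @seealso [predict.ref_limits()] to flag an audit cohort,
#'   [simulate.ref_limits()] to draw synthetic cohorts from the fit.
#' @export
#' @examples
#' set.seed(7)
#' ref <- data.frame(organ = "brainstem", dsc = rnorm(50, 0.81, 0.06))
#' fit <- fit_reference_limits(ref)
#' fit
#' coef(fit)
fit_reference_limits <- function(data, organ = NULL, hd = NULL) {
  if (is.numeric(data)) {
    if (is.null(organ)) {
      stop_segqa("'organ' is required when 'data' is a numeric vector",
                 "segqa_validation_error")
    }
    data <- data.frame(organ = organ, dsc = data,
                       hd95_2d = if (is.null(hd)) NA_real_ else hd)
  }
  if (!all(c("organ", "dsc") %in% names(data))) {
    stop_segqa("'data' needs columns 'organ' and 'dsc'", "segqa_validation_error")
  }
  if (!"hd95_2d" %in% names(data)) data$hd95_2d <- NA_real_
  rows <- lapply(split(data, data$organ), function(d) {
    dsc <- d$dsc[is.finite(d$dsc)]
    if (length(dsc) < 2L) {
      stop_segqa(sprintf("organ '%s': need at least 2 finite DSC values",
                         d$organ[1]), "segqa_insufficient_data_error")
    }
    if (any(dsc < 0 | dsc > 1)) {
      stop_segqa(sprintf("organ '%s': DSC values outside [0, 1]", d$organ[1]),
                 "segqa_domain_error")
    }
    hdv <- d$hd95_2d[is.finite(d$hd95_2d)]
    hd_mean <- hd_sd <- hd_up <- NA_real_
    if (length(hdv) >= 2L) {
      if (any(hdv < 0)) {
        stop_segqa(sprintf("organ '%s': negative HD95 values", d$organ[1]),
                   "segqa_domain_error")
      }
      hd_mean <- mean(hdv); hd_sd <- stats::sd(hdv)
      hd_up <- hd_mean + 3 * hd_sd
    }
    m <- mean(dsc); s <- stats::sd(dsc)
    data.frame(organ = d$organ[1], dsc_mean = m, dsc_sd = s,
               dsc_lower_limit = max(0, m - 3 * s),
               hd_mean = hd_mean, hd_sd = hd_sd, hd_upper_limit = hd_up,
               n_reference = length(dsc), stringsAsFactors = FALSE)
  })
  limits <- do.call(rbind, rows)
  rownames(limits) <- NULL
  structure(list(limits = limits, call = match.call()), class = "ref_limits")
}

#' Reference limits from known per-organ mean and SD
#'
#' Builds a `ref_limits` object directly from published or externally
#' estimated cohort statistics instead of patient-level values — e.g. from a
#' table of per-organ DSC mean +/- SD of a reference cohort.
#'
#' @param organ Character vector of organ labels.
#' @param dsc_mean,dsc_sd Per-organ DSC mean and standard deviation.
#' @param hd_mean,hd_sd Optional per-organ HD95 statistics, mm.
#' @param n_reference Cohort size(s) the statistics were estimated from.
#' @return A `ref_limits` object (see [fit_reference_limits()]).
#' @export
#' @examples
#' reference_limits(c("brainstem", "mandible"),
#'                  dsc_mean = c(0.81, 0.91), dsc_sd = c(0.06, 0.02))
reference_limits <- function(organ, dsc_mean, dsc_sd,
                             hd_mean = NA_real_, hd_sd = NA_real_,
                             n_reference = NA_integer_) {
  stopifnot(length(organ) == length(dsc_mean), length(organ) == length(dsc_sd))
  if (any(dsc_mean < 0 | dsc_mean > 1)) {
    stop_segqa("DSC means must lie in [0, 1]", "segqa_domain_error")
  }
  if (any(dsc_sd < 0) || any(!is.na(hd_sd) & hd_sd < 0)) {
    stop_segqa("standard deviations must be non-negative", "segqa_domain_error")
  }
  limits <- data.frame(
    organ = organ, dsc_mean = dsc_mean, dsc_sd = dsc_sd,
    dsc_lower_limit = pmax(0, dsc_mean - 3 * dsc_sd),
    hd_mean = rep_len(hd_mean, length(organ)),
    hd_sd = rep_len(hd_sd, length(organ)),
    hd_upper_limit = rep_len(hd_mean, length(organ)) + 3 * rep_len(hd_sd, length(organ)),
    n_reference = rep_len(as.integer(n_reference), length(organ)),
    stringsAsFactors = FALSE)
  structure(list(limits = limits, call = match.call()), class = "ref_limits")
}

#' @export
print.ref_limits <- function(x, digits = 3, ...) {
  cat("Three-sigma gross-failure reference limits\n\n")
  lim <- x$limits
  out <- data.frame(organ = lim$organ,
                    dsc = sprintf(paste0("%.", digits - 1, "f ± %.", digits - 1, "f"),
                                  lim$dsc_mean, lim$dsc_sd),
                    dsc_lower_limit = signif(lim$dsc_lower_limit, digits),
                    hd_upper_limit = ifelse(is.na(lim$hd_upper_limit), "-",
                                            sprintf("%.1f mm", lim$hd_upper_limit)),
                    n = lim$n_reference)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ref_limits <- function(object, ...) {
  structure(list(limits = object$limits), class = "summary.ref_limits")
}

#' @export
print.summary.ref_limits <- function(x, ...) {
  cat("Per-organ reference statistics and three-sigma limits:\n")
  print(x$limits, row.names = FALSE)
  cat("\nA result is a gross failure when dsc < dsc_lower_limit",
      "(strictly below); when an HD limit is present, hd95_2d >",
      "hd_upper_limit flags independently.\n")
  invisible(x)
}

#' @export
coef.ref_limits <- function(object, ...) {
  m <- as.matrix(object$limits[, c("dsc_mean", "dsc_sd", "dsc_lower_limit",
                                   "hd_mean", "hd_sd", "hd_upper_limit")])
  rownames(m) <- object$limits$organ
  m
}

#' Flag gross failures in an audit cohort
#'
#' Applies fitted three-sigma limits to new metric results. A result fails
#' on DSC when `dsc < dsc_lower_limit` (strict: a value exactly at the limit
#' is in control); it fails on HD when an HD limit exists, `hd95_2d` is
#' defined, and `hd95_2d > hd_upper_limit` (strict). An undefined `hd95_2d`
#' (no shared slice) yields `hd_failed = NA`, never a silent `FALSE`.
#'
#' @param object A `ref_limits` fit.
#' @param newdata Data frame of audit metric results with columns `organ`
#'   and `dsc`, optionally `patient_id` and `hd95_2d`.
#' @param ... Unused.
#' @return `newdata` with columns `dsc_lower_limit`, `hd_upper_limit`,
#'   `dsc_failed` (logical) and `hd_failed` (logical, `NA` when
#'   undefined) appended; class `c("qa_flags", "data.frame")`.
#' @export
predict.ref_limits <- function(object, newdata, ...) {
  if (!all(c("organ", "dsc") %in% names(newdata))) {
    stop_segqa("'newdata' needs columns 'organ' and 'dsc'", "segqa_validation_error")
  }
  lim <- object$limits
  idx <- match(newdata$organ, lim$organ)
  if (anyNA(idx)) {
    stop_segqa(sprintf("no reference limits for organ(s): %s",
                       paste(unique(newdata$organ[is.na(idx)]), collapse = ", ")),
               "segqa_routing_error")
  }
  out <- newdata
  out$dsc_lower_limit <- lim$dsc_lower_limit[idx]
  out$hd_upper_limit <- lim$hd_upper_limit[idx]
  out$dsc_failed <- out$dsc < out$dsc_lower_limit
  if ("hd95_2d" %in% names(out)) {
    out$hd_failed <- ifelse(is.na(out$hd95_2d), NA,
                            ifelse(is.na(out$hd_upper_limit), NA,
                                   out$hd95_2d > out$hd_upper_limit))
  } else {
    out$hd_failed <- NA
  }
  class(out) <- c("qa_flags", class(newdata))
  out
}

#' @rdname predict.ref_limits
#' @param results Data frame of metric results (alias interface).
#' @param limits A `ref_limits` fit.
#' @export
flag_gross_failures <- function(results, limits) {
  predict(limits, results)
}

#' Draw synthetic DSC cohorts from fitted limits
#'
#' Simulates per-organ DSC values from the fitted reference statistics as a
#' normal distribution truncated to `(0, 1]` — the distributional model
#' underlying the three-sigma rule.
#'
#' @param object A `ref_limits` fit.
#' @param nsim Number of values per organ.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param ... Unused.
#' @return Data frame with columns `organ` and `dsc` (`nsim` rows per organ).
#' @export
simulate.ref_limits <- function(object, nsim = 1, seed = NULL, ...) {
  lim <- object$limits
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(lim)), function(i) {
      data.frame(organ = lim$organ[i],
                 dsc = rnorm_truncated(nsim, lim$dsc_mean[i], lim$dsc_sd[i]),
                 stringsAsFactors = FALSE)
    }))
  })
}

# Normal(mean, sd) truncated to (0, 1] by inverse-CDF sampling
rnorm_truncated <- function(n, mean, sd, lower = 0, upper = 1) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + (phi - plo) * stats::runif(n), mean, sd)
}

#' Plot an audit cohort against its reference limits
#'
#' Draws, per organ, the per-patient DSC series with the lower three-sigma
#' gross-failure limit as a horizontal line and flagged results highlighted —
#' the standard control-chart view of an auto-segmentation audit.
#'
#' @param x A `ref_limits` fit.
#' @param metrics Data frame of metric results with columns `organ`, `dsc`.
#' @param organs Organs to plot (default: all organs in the fit that appear
#'   in `metrics`).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the flagged data (see [predict.ref_limits()]).
#' @export
plot.ref_limits <- function(x, metrics = NULL, organs = NULL, ...) {
  lim <- x$limits
  if (is.null(metrics)) {
    # no cohort: show limits as a dot-and-bar chart
    graphics::plot(seq_len(nrow(lim)), lim$dsc_mean, ylim = c(0, 1),
                   xaxt = "n", xlab = "", ylab = "DSC",
                   pch = 19, main = "Reference DSC and three-sigma limits", ...)
    graphics::axis(1, at = seq_len(nrow(lim)), labels = lim$organ, las = 2)
    graphics::segments(seq_len(nrow(lim)), lim$dsc_lower_limit,
                       seq_len(nrow(lim)), pmin(1, lim$dsc_mean + 3 * lim$dsc_sd))
    return(invisible(NULL))
  }
  flags <- predict(x, metrics)
  if (is.null(organs)) organs <- intersect(lim$organ, unique(metrics$organ))
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(organs)))
  on.exit(graphics::par(op), add = TRUE)
  for (org in organs) {
    d <- flags[flags$organ == org, ]
    graphics::plot(seq_len(nrow(d)), d$dsc, ylim = c(0, 1),
                   xlab = "patient index", ylab = "DSC", main = org,
                   col = ifelse(d$dsc_failed, "red", "grey30"),
                   pch = ifelse(d$dsc_failed, 19, 1), ...)
    graphics::abline(h = d$dsc_lower_limit[1], lty = 2, col = "red")
  }
  invisible(flags)
}

#' Write / read reference limits as CSV
#'
#' @param object A `ref_limits` fit.
#' @param path File path.
#' @return `write_limits_csv()` returns `path` invisibly;
#'   `read_limits_csv()` returns a `ref_limits` object.
#' @export
write_limits_csv <- function(object, path) {
  stopifnot(inherits(object, "ref_limits"))
  utils::write.csv(object$limits, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_limits_csv
#' @export
read_limits_csv <- function(path) {
  lim <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(organ = "character"))
  need <- c("organ", "dsc_mean", "dsc_sd", "dsc_lower_limit",
            "hd_mean", "hd_sd", "hd_upper_limit", "n_reference")
  miss <- setdiff(need, names(lim))
  if (length(miss)) {
    stop_segqa(paste("limits file missing columns:", paste(miss, collapse = ", ")),
               "segqa_validation_error")
  }
  structure(list(limits = lim[, need], call = sys.call()), class = "ref_limits")
}
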