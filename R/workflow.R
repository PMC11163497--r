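#' Pipeline configuration
#'
#' Collects the knobs shared by [run_calibrate()] and [run_audit()]. Values
#' may come from a flat `key = value` text file ([read_config()]) with
#' individual arguments overriding file entries.
#'
#' @param organs Character vector of organ names (non-empty).
#' @param format Input contour format: `"contour-json"`, `"dicom-rt"` or
#'   `"nifti-masks"`.
#' @param spacing In-plane pixel size, mm (length 1 or 2, > 0).
#' @param sampling_step Boundary resampling step for HD95, mm (> 0).
#' @param limits Path to a limits CSV ([write_limits_csv()]).
#' @param annotations Path to a review annotation CSV.
#' @param out Output directory.
#' @param seed Integer seed for any stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(organs, format = "contour-json",
                            spacing = 1, sampling_step = 0.5,
                            limits = NULL, annotations = NULL,
                            out = ".", seed = 1) {
  if (!length(organs)) stop_segqa("organ list is empty", "segqa_validation_error")
  spacing <- rep_len(as.numeric(spacing), 2L)
  if (any(spacing <= 0) || sampling_step <= 0) {
    stop_segqa("spacing and sampling_step must be positive", "segqa_validation_error")
  }
  structure(list(organs = organs, format = format, spacing = spacing,
                 sampling_step = sampling_step, limits = limits,
                 annotations = annotations, out = out, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a flat `key = value` configuration file; `organs`
#'   is comma-separated. Lines starting with `#` are ignored.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)))
  args <- stats::setNames(as.list(vals), keys)
  if (!is.null(args$organs)) args$organs <- trimws(strsplit(args$organs, ",")[[1]])
  for (num in c("spacing", "sampling_step", "seed")) {
    if (!is.null(args[[num]])) args[[num]] <- as.numeric(strsplit(args[[num]], ",")[[1]])
  }
  do.call(pipeline_config, args)
}

# metric table for a set of pairs under one config
compute_metrics <- function(pairs, config) {
  do.call(rbind, lapply(pairs, function(p) {
    compare_pair(p, spacing = config$spacing,
                 sampling_step = config$sampling_step)
  }))
}

# locate the gold/auto files of a generated cohort directory
cohort_pair_files <- function(dir, manifest, format = "contour-json") {
  ext <- switch(format, "contour-json" = "json", "dicom-rt" = "dcm",
                "nifti-masks" = "nii")
  data.frame(
    gold = file.path(dir, sprintf("%s_%s_gold.%s", manifest$patient_id,
                                  manifest$organ, ext)),
    auto = file.path(dir, sprintf("%s_%s_auto.%s", manifest$patient_id,
                                  manifest$organ, ext)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic phantom cohort on disk
#'
#' Writes a [simulate_contour_cohort()] cohort as contour-JSON files (one
#' per structure) plus a manifest CSV recording the injected perturbation
#' for every pair, and a provenance JSON echoing the call.
#'
#' @param out Output directory.
#' @param n_patients Patients per organ.
#' @param organs Organs to generate.
#' @param failure_prob Injected gross-failure probability.
#' @param seed Integer seed.
#' @return Invisibly, the cohort object (with `manifest`).
#' @export
run_generate <- function(out, n_patients, organs = organ_archetypes()$organ,
                         failure_prob = 0.012, seed = 1) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  coh <- simulate_contour_cohort(n_patients, organs = organs,
                                 failure_prob = failure_prob, seed = seed)
  files <- cohort_pair_files(out, coh$manifest)
  for (i in seq_along(coh$pairs)) {
    write_contour_json(coh$pairs[[i]]$gold, files$gold[i])
    write_contour_json(coh$pairs[[i]]$auto, files$auto[i])
  }
  utils::write.csv(coh$manifest, file.path(out, "manifest.csv"), row.names = FALSE)
  write_provenance(out, "generate",
                   list(n_patients = n_patients, organs = organs,
                        failure_prob = failure_prob, seed = seed))
  invisible(coh)
}

#' Calibrate reference limits from a reference cohort
#'
#' Phase one of the QA procedure: compare every gold/auto pair of the
#' reference cohort, fit per-organ three-sigma limits, and write them to
#' `limits.csv` in the output directory (plus the metric table and a
#' provenance record). At least two pairs per organ are required.
#'
#' @param config A [pipeline_config()].
#' @param pairs List of [structure_pair()] objects, or a data frame with
#'   columns `gold`, `auto` (file paths), `organ`, `patient_id` to be read
#'   with `config$format`.
#' @return The fitted `ref_limits` object, invisibly.
#' @export
run_calibrate <- function(config, pairs) {
  pairs <- resolve_pairs(pairs, config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  metrics <- compute_metrics(pairs, config)
  counts <- table(metrics$organ)
  if (any(counts < 2)) {
    stop_segqa(sprintf("fewer than 2 reference pairs for organ(s): %s",
                       paste(names(counts)[counts < 2], collapse = ", ")),
               "segqa_insufficient_data_error")
  }
  fit <- fit_reference_limits(metrics)
  write_metrics_csv(metrics, file.path(config$out, "reference_metrics.csv"))
  write_limits_csv(fit, file.path(config$out, "limits.csv"))
  write_provenance(config$out, "calibrate",
                   list(organs = config$organs, spacing = config$spacing,
                        sampling_step = config$sampling_step,
                        n_pairs = length(pairs), seed = config$seed))
  message(sprintf("calibrated %d organ(s) from %d pair(s); limits written to %s",
                  nrow(fit$limits), length(pairs),
                  file.path(config$out, "limits.csv")))
  for (i in seq_len(nrow(fit$limits))) {
    message(sprintf("  %s: DSC %.3f ± %.3f, lower limit %.3f",
                    fit$limits$organ[i], fit$limits$dsc_mean[i],
                    fit$limits$dsc_sd[i], fit$limits$dsc_lower_limit[i]))
  }
  invisible(fit)
}

#' Audit a test cohort against reference limits
#'
#' Phase two of the QA procedure: compare every audited gold/auto pair,
#' flag gross failures against the fitted limits, route the flags through
#' expert review annotations, and write the metric table, flag table and
#' failure-rate report. In flag-only mode the run stops after flagging
#' (no annotations required, no report).
#'
#' @param config A [pipeline_config()]; `config$limits` must point to a
#'   limits CSV unless `limits` is given.
#' @param pairs As in [run_calibrate()].
#' @param limits Optional `ref_limits` object (overrides `config$limits`).
#' @param annotations Optional annotation data frame (overrides
#'   `config$annotations`).
#' @param flag_only Stop after flagging.
#' @param n_evaluated Per-organ denominators for the report; defaults to
#'   the number of audited pairs per organ.
#' @return A list with `metrics`, `flags` and (unless `flag_only`)
#'   `records` and `summary`; `n_failures` gives the flagged count so
#'   callers can distinguish "no failures" from "failures present".
#' @export
run_audit <- function(config, pairs, limits = NULL, annotations = NULL,
                      flag_only = FALSE, n_evaluated = NULL) {
  if (is.null(limits)) {
    if (is.null(config$limits)) {
      stop_segqa("no limits given and config$limits is unset", "segqa_config_error")
    }
    limits <- read_limits_csv(config$limits)
  }
  miss <- setdiff(config$organs, limits$limits$organ)
  if (length(miss)) {
    stop_segqa(paste("no reference limits for organ(s):",
                     paste(miss, collapse = ", ")), "segqa_config_error")
  }
  pairs <- resolve_pairs(pairs, config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  if (!length(pairs)) {
    warning("audit cohort is empty; writing header-only outputs", call. = FALSE)
    metrics <- utils::read.csv(text = paste(
      "patient_id,organ,dsc,hd95_2d,n_shared_slices,n_gold_only_slices,n_auto_only_slices"))
    write_metrics_csv(metrics, file.path(config$out, "audit_metrics.csv"))
    return(invisible(list(metrics = metrics, flags = NULL, n_failures = 0L)))
  }
  metrics <- compute_metrics(pairs, config)
  flags <- predict(limits, metrics)
  write_metrics_csv(metrics, file.path(config$out, "audit_metrics.csv"))
  utils::write.csv(flags, file.path(config$out, "audit_flags.csv"),
                   row.names = FALSE, na = "")
  out <- list(metrics = metrics, flags = flags,
              n_failures = sum(flags$dsc_failed))
  if (!flag_only) {
    if (is.null(annotations) && !is.null(config$annotations)) {
      annotations <- read_annotations_csv(config$annotations)
    }
    records <- apply_review(flags, annotations)
    summary <- summarize_cohort(records, n_evaluated = n_evaluated)
    write_report(summary, config$out)
    utils::write.csv(plot_data(flags), file.path(config$out, "audit_plotdata.csv"),
                     row.names = FALSE)
    out$records <- records
    out$summary <- summary
  }
  write_provenance(config$out, "audit",
                   list(organs = config$organs, spacing = config$spacing,
                        sampling_step = config$sampling_step,
                        limits = config$limits, flag_only = flag_only,
                        n_pairs = length(pairs), seed = config$seed))
  message(sprintf("audited %d pair(s): %d gross failure(s) flagged",
                  length(pairs), out$n_failures))
  invisible(out)
}

resolve_pairs <- function(pairs, config) {
  if (is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i) {
      read_structure_pair(pairs$gold[i], pairs$auto[i], format = config$format,
                          organ = pairs$organ[i],
                          patient_id = pairs$patient_id[i])
    })
  }
  stopifnot(all(vapply(pairs, inherits, logical(1), "structure_pair")))
  pairs
}

write_provenance <- function(dir, stage, params) {
  jsonlite::write_json(
    list(stage = stage, params = params,
         package = as.character(utils::packageVersion("segqa")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(dir, paste0(stage, "_provenance.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(NULL)
}
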