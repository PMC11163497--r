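#' Failure review verdicts
#'
#' The closed set of expert-review verdicts: a flagged comparison is either
#' censored because the manual (gold) contour was judged suboptimal, or is a
#' true failure of the auto-segmentation assigned to one of four modes —
#' non-standard patient setup position, non-standard internal anatomy
#' (e.g. post-surgery), CT image artefacts in the region (e.g. dental
#' fillings), or no obvious reason.
#'
#' @return Character vector of valid verdict tokens.
#' @export
review_verdicts <- function() {
  c("censored_suboptimal_manual", "setup", "anatomy", "artefacts", "unknown")
}

failure_categories <- function() c("setup", "anatomy", "artefacts", "unknown")

#' Apply expert review annotations to gross-failure flags
#'
#' Review is an explicit human input, never automated: every DSC-flagged
#' comparison must carry exactly one annotation identifying it as either a
#' censored suboptimal manual contour or a true failure with its mode.
#' Non-flagged results need no annotation and become `not_failed`.
#'
#' @param flags Flagged metric results from [predict.ref_limits()] (columns
#'   `patient_id`, `organ`, `dsc_failed` at minimum).
#' @param annotations Data frame with columns `patient_id`, `organ`,
#'   `verdict` (one of [review_verdicts()]) and optionally `note`; matched
#'   to flags on `(patient_id, organ)`.
#' @return `flags` with columns `status` (`not_failed` / `censored` /
#'   `true_failure`), `category` (failure mode, `NA` unless a true failure)
#'   and `note` appended; class `c("failure_records", ...)`.
#' @details Errors: a flagged result without an annotation
#'   (incomplete review), duplicate annotations for one result (conflict),
#'   or an invalid verdict token. An annotation pointing at a non-flagged
#'   result raises a warning (orphan annotation) and is ignored.
#' @export
#' @examples
#' flags <- data.frame(patient_id = c("p1", "p2"), organ = "brainstem",
#'                     dsc = c(0.4, 0.8), dsc_failed = c(TRUE, FALSE))
#' ann <- data.frame(patient_id = "p1", organ = "brainstem", verdict = "setup")
#' apply_review(flags, ann)
apply_review <- function(flags, annotations = NULL) {
  need <- c("patient_id", "organ", "dsc_failed")
  if (!all(need %in% names(flags))) {
    stop_segqa("'flags' needs columns patient_id, organ, dsc_failed",
               "segqa_validation_error")
  }
  if (is.null(annotations)) {
    annotations <- data.frame(patient_id = character(), organ = character(),
                              verdict = character(), note = character())
  }
  if (!"note" %in% names(annotations)) annotations$note <- NA_character_
  bad <- setdiff(annotations$verdict, review_verdicts())
  if (length(bad)) {
    stop_segqa(paste("invalid verdict token(s):", paste(unique(bad), collapse = ", ")),
               "segqa_validation_error")
  }
  fkey <- paste(flags$patient_id, flags$organ, sep = "\r")
  akey <- paste(annotations$patient_id, annotations$organ, sep = "\r")
  if (anyDuplicated(akey)) {
    stop_segqa("duplicate annotation for the same (patient, organ)",
               "segqa_conflict_error")
  }
  idx <- match(fkey, akey)
  flagged <- flags$dsc_failed
  missing_ann <- flagged & is.na(idx)
  if (any(missing_ann)) {
    stop_segqa(sprintf("incomplete review: %d flagged result(s) without annotation (e.g. %s / %s)",
                       sum(missing_ann), flags$patient_id[missing_ann][1],
                       flags$organ[missing_ann][1]),
               "segqa_incomplete_review_error")
  }
  orphan <- setdiff(akey, fkey[flagged])
  if (length(orphan)) {
    warning(sprintf("%d annotation(s) refer to non-flagged results and are ignored",
                    length(orphan)), call. = FALSE)
  }
  verdict <- annotations$verdict[idx]
  out <- flags
  out$status <- ifelse(!flagged, "not_failed",
                       ifelse(verdict == "censored_suboptimal_manual",
                              "censored", "true_failure"))
  out$category <- ifelse(out$status == "true_failure", verdict, NA_character_)
  out$note <- ifelse(flagged, annotations$note[idx], NA_character_)
  class(out) <- unique(c("failure_records", class(flags)))
  out
}

#' Read / write review annotations as CSV
#'
#' Columns: `patient_id`, `organ`, `verdict` (exactly one of
#' [review_verdicts()]), `note`.
#'
#' @param path File path.
#' @param annotations Annotation data frame.
#' @return `read_annotations_csv()` returns the data frame;
#'   `write_annotations_csv()` returns `path` invisibly.
#' @export
read_annotations_csv <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character", organ = "character"))
  if (!all(c("patient_id", "organ", "verdict") %in% names(ann))) {
    stop_segqa("annotations CSV needs columns patient_id, organ, verdict",
               "segqa_validation_error")
  }
  ann
}

#' @rdname read_annotations_csv
#' @export
write_annotations_csv <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE, na = "")
  invisible(path)
}
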