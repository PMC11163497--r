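#' Read a NIfTI binary mask as a contour stack
#'
#' Loads one binary structure volume from a NIfTI file and converts it to
#' planar contours by per-slice boundary tracing ([trace_mask()]). Only
#' axis-aligned affines are supported: the voxel axes must map onto the
#' patient axes without rotation or shear (diagonal affine up to axis
#' sign); spacing and origin are taken from the affine.
#'
#' @param path Path to a `.nii` / `.nii.gz` file holding a single binary
#'   (0/1) volume.
#' @param organ Organ label for the resulting stack.
#' @param threshold Voxels with intensity strictly above this are foreground.
#' @return A [contour_stack()].
#' @export
read_nifti_mask <- function(path, organ = "structure", threshold = 0.5) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  if (length(dim(img)) != 3L) {
    stop_segqa(sprintf("'%s': expected a 3D volume", path), "segqa_io_error")
  }
  rot <- aff[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-6 * max(abs(rot)))) {
    stop_segqa(sprintf("'%s': only axis-aligned NIfTI affines are supported", path),
               "segqa_io_error")
  }
  spacing <- abs(diag(rot))
  if (any(spacing <= 0)) {
    stop_segqa(sprintf("'%s': degenerate voxel spacing", path), "segqa_io_error")
  }
  vox <- array(as.vector(img) > threshold, dim = dim(img))
  origin <- aff[1:3, 4]
  # flip axes with negative direction so voxel index increases with coordinate
  for (ax in 1:3) {
    if (diag(rot)[ax] < 0) {
      idx <- rev(seq_len(dim(vox)[ax]))
      vox <- switch(ax, vox[idx, , , drop = FALSE], vox[, idx, , drop = FALSE],
                    vox[, , idx, drop = FALSE])
      origin[ax] <- origin[ax] + diag(rot)[ax] * (dim(vox)[ax] - 1)
    }
  }
  grid <- voxel_grid(origin = origin, spacing = spacing, dim = dim(vox))
  trace_mask(binary_mask(grid, vox), organ = organ)
}

#' Write a binary mask to NIfTI
#'
#' Counterpart of [read_nifti_mask()] for building fixtures and exporting
#' rasterized structures; writes an axis-aligned affine from the grid's
#' spacing and origin.
#'
#' @param mask A [binary_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  g <- mask$grid
  arr <- array(as.integer(mask$voxels), dim = g$dim)
  aff <- diag(c(g$spacing, 1))
  aff[1:3, 4] <- g$origin
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a gold/auto structure pair from files
#'
#' Front door for the three supported on-disk representations:
#'
#' * `"contour-json"` — one contour JSON file per structure;
#' * `"dicom-rt"` — one DICOM-RT structure set per structure (or the same
#'   file twice with different ROI names), `organ` selecting the ROI;
#' * `"nifti-masks"` — one binary NIfTI volume per structure, converted to
#'   contours by boundary tracing.
#'
#' For DICOM-RT, the two files' frame-of-reference UIDs must agree —
#' contours from different frames of reference are not comparable.
#'
#' @param gold_path,auto_path Paths to the gold-standard and auto structure.
#' @param format One of `"contour-json"`, `"dicom-rt"`, `"nifti-masks"`.
#' @param organ Organ / ROI name; required for `"dicom-rt"`, used as the
#'   stack label for `"nifti-masks"`, and checked against the stored organ
#'   for `"contour-json"` when given.
#' @param patient_id Patient label for the pair; for DICOM-RT defaults to
#'   the file's PatientID.
#' @return A [structure_pair()].
#' @export
read_structure_pair <- function(gold_path, auto_path,
                                format = c("contour-json", "dicom-rt", "nifti-masks"),
                                organ = NULL, patient_id = NULL) {
  format <- match.arg(format)
  for (p in c(gold_path, auto_path)) {
    if (!file.exists(p)) {
      stop_segqa(sprintf("input file not found: %s", p), "segqa_io_error")
    }
  }
  if (format == "contour-json") {
    gold <- read_contour_json(gold_path)
    auto <- read_contour_json(auto_path)
    if (!is.null(organ) && !identical(gold$organ, organ)) {
      stop_segqa(sprintf("'%s' holds organ '%s', not '%s'", gold_path,
                         gold$organ, organ), "segqa_lookup_error")
    }
  } else if (format == "dicom-rt") {
    if (is.null(organ)) {
      stop_segqa("'organ' (ROI name) is required for dicom-rt input",
                 "segqa_validation_error")
    }
    g <- read_dicom_rt(gold_path)
    a <- read_dicom_rt(auto_path)
    if (!is.na(g$frame_of_reference) && !is.na(a$frame_of_reference) &&
        !identical(g$frame_of_reference, a$frame_of_reference)) {
      stop_segqa("gold and auto structure sets use different frames of reference",
                 "segqa_consistency_error")
    }
    gold <- dicom_rt_stack(g, organ)
    auto <- dicom_rt_stack(a, organ)
    if (is.null(patient_id)) patient_id <- g$patient_id
  } else {
    if (is.null(organ)) organ <- "structure"
    gold <- read_nifti_mask(gold_path, organ = organ)
    auto <- read_nifti_mask(auto_path, organ = organ)
  }
  if (is.null(patient_id)) patient_id <- "unknown"
  structure_pair(patient_id, gold, auto)
}
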