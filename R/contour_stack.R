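#' Planar contour stack
#'
#' A `contour_stack` represents one organ structure as closed planar polygons
#' on ordered axial CT slices, in patient-space millimetres (x/y in-plane,
#' z superior-inferior). A slice may carry several polygons (multi-part
#' cross-sections, e.g. a mandible ramus pair or an artefact-split organ);
#' holes are expressed through the even-odd fill rule used by [rasterize()].
#'
#' @param organ Organ label (single string).
#' @param slices List of slices, each a list with elements `z` (slice
#'   position, mm) and `polygons` (list of numeric n x 2 matrices of (x, y)
#'   vertices, mm). Polygons are implicitly closed: the last vertex connects
#'   back to the first. Slices are sorted by `z` on construction.
#' @return An object of class `contour_stack`.
#' @details Invariants enforced: strictly increasing z positions (duplicate
#'   z is an error), every polygon has at least 3 vertices and finite
#'   coordinates.
#' @seealso [rasterize()], [make_phantom()], [read_contour_json()]
#' @export
#' @examples
#' sq <- cbind(c(-5, 5, 5, -5), c(-5, -5, 5, 5))
#' cs <- contour_stack("brainstem", list(list(z = 0, polygons = list(sq))))
#' cs
contour_stack <- function(organ, slices) {
  if (!is.character(organ) || length(organ) != 1L || !nzchar(organ)) {
    stop_segqa("'organ' must be a single non-empty string", "segqa_validation_error")
  }
  if (!is.list(slices)) {
    stop_segqa("'slices' must be a list", "segqa_validation_error")
  }
  slices <- lapply(slices, function(s) {
    if (!is.list(s) || is.null(s$z) || is.null(s$polygons)) {
      stop_segqa("each slice needs 'z' and 'polygons'", "segqa_validation_error")
    }
    if (!is_scalar_number(s$z)) {
      stop_segqa("slice 'z' must be a finite number", "segqa_validation_error")
    }
    polys <- lapply(s$polygons, function(p) {
      p <- as.matrix(p)
      storage.mode(p) <- "double"
      if (ncol(p) != 2L || nrow(p) < 3L || !all(is.finite(p))) {
        stop_segqa("each polygon must be a finite n x 2 matrix with n >= 3",
                   "segqa_validation_error")
      }
      dimnames(p) <- NULL
      p
    })
    list(z = as.numeric(s$z), polygons = polys)
  })
  z <- vapply(slices, `[[`, numeric(1), "z")
  if (anyDuplicated(z)) {
    stop_segqa("duplicate slice z positions in one stack", "segqa_validation_error")
  }
  slices <- slices[order(z)]
  structure(list(organ = organ, slices = slices), class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  z <- slice_z(x)
  np <- sum(vapply(x$slices, function(s) length(s$polygons), integer(1)))
  cat(sprintf("<contour_stack> organ '%s': %d slice(s), %d polygon(s)\n",
              x$organ, length(z), np))
  if (length(z)) {
    cat(sprintf("  z range [%g, %g] mm\n", min(z), max(z)))
  }
  invisible(x)
}

# z positions of a stack, in increasing order
slice_z <- function(stack) {
  vapply(stack$slices, `[[`, numeric(1), "z")
}

#' Pair of gold-standard and auto-generated structures
#'
#' Bundles the expert manual ("gold standard") contour and the AI-generated
#' contour of the same organ for one patient.
#'
#' @param patient_id Patient label.
#' @param gold,auto `contour_stack` objects for the same organ.
#' @return An object of class `structure_pair`.
#' @export
structure_pair <- function(patient_id, gold, auto) {
  stopifnot(inherits(gold, "contour_stack"), inherits(auto, "contour_stack"))
  if (!identical(gold$organ, auto$organ)) {
    stop_segqa(sprintf("organ mismatch between gold ('%s') and auto ('%s')",
                       gold$organ, auto$organ), "segqa_validation_error")
  }
  if (!is.character(patient_id) || length(patient_id) != 1L) {
    stop_segqa("'patient_id' must be a single string", "segqa_validation_error")
  }
  structure(list(patient_id = patient_id, organ = gold$organ,
                 gold = gold, auto = auto),
            class = "structure_pair")
}

#' @export
print.structure_pair <- function(x, ...) {
  cat(sprintf("<structure_pair> patient '%s', organ '%s' (gold %d / auto %d slices)\n",
              x$patient_id, x$organ, length(x$gold$slices), length(x$auto$slices)))
  invisible(x)
}

#' Regular voxel grid
#'
#' Defines the regular CT-like grid that contours are rasterized onto. The
#' origin is the centre of the first voxel; voxel centres lie at
#' `origin + (i - 1) * spacing`.
#'
#' @param origin Numeric length-3, (x, y, z) of the first voxel centre, mm.
#' @param spacing Numeric length-3, voxel spacing (dx, dy, dz), mm; all > 0.
#' @param dim Integer length-3 voxel counts (nx, ny, nz); all >= 1.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(origin, spacing, dim) {
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  dim <- as.integer(dim)
  if (length(origin) != 3L || length(spacing) != 3L || length(dim) != 3L ||
      !all(is.finite(origin)) || !all(is.finite(spacing))) {
    stop_segqa("origin, spacing and dim must be finite length-3 vectors",
               "segqa_validation_error")
  }
  if (any(spacing <= 0)) stop_segqa("spacing must be positive", "segqa_validation_error")
  if (any(dim < 1L)) stop_segqa("dim must be >= 1", "segqa_validation_error")
  structure(list(origin = origin, spacing = spacing, dim = dim),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d, spacing %g x %g x %g mm, origin (%g, %g, %g)\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

grid_z_planes <- function(grid) grid$origin[3] + (seq_len(grid$dim[3]) - 1) * grid$spacing[3]

same_grid <- function(a, b, tol = 1e-9) {
  identical(a$dim, b$dim) &&
    all(abs(a$origin - b$origin) <= tol) &&
    all(abs(a$spacing - b$spacing) <= tol)
}

#' Build a voxel grid that covers one or more contour stacks
#'
#' Computes an axis-aligned grid whose xy extent covers all polygons (plus a
#' margin) and whose z planes coincide with the union of the stacks' slice
#' positions. Slice positions must lie on a common regular grid within
#' `dz/2` or rasterization would be ill-defined.
#'
#' @param ... `contour_stack` objects.
#' @param spacing In-plane pixel size `c(dx, dy)` in mm (default 1 x 1 mm,
#'   a representative head-and-neck CT pixel).
#' @param margin Extra xy margin around the joint bounding box, mm.
#' @return A [voxel_grid()].
#' @export
fit_grid <- function(..., spacing = c(1, 1), margin = 2) {
  stacks <- list(...)
  stopifnot(length(stacks) > 0)
  all_z <- sort(unique(unlist(lapply(stacks, slice_z))))
  if (length(all_z) == 0) stop_segqa("no slices in input stacks", "segqa_validation_error")
  if (length(all_z) > 1) {
    dz <- min(diff(all_z))
    # merge z values closer than dz/2 (same physical plane)
    keep <- c(TRUE, diff(all_z) > dz / 2)
    all_z <- all_z[keep]
    nz <- round((max(all_z) - min(all_z)) / dz) + 1L
    planes <- min(all_z) + (seq_len(nz) - 1L) * dz
    off <- vapply(all_z, function(z) min(abs(z - planes)), numeric(1))
    if (any(off > dz / 2 + 1e-9)) {
      stop_segqa("slice z positions do not lie on a regular grid",
                 "segqa_alignment_error")
    }
  } else {
    dz <- 2
    nz <- 1L
  }
  xy <- do.call(rbind, unlist(lapply(stacks, function(s) {
    lapply(s$slices, function(sl) do.call(rbind, sl$polygons))
  }), recursive = FALSE))
  lo <- apply(xy, 2, min) - margin
  hi <- apply(xy, 2, max) + margin
  n_xy <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  voxel_grid(origin = c(lo, min(all_z)),
             spacing = c(spacing, dz),
             dim = c(n_xy, nz))
}
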