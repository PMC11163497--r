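#' 3D Dice similarity coefficient
#'
#' Volume-overlap agreement between two structures on a shared voxel grid:
#' `2|A ∩ B| / (|A| + |B|)`, 1 for identical masks and 0 for disjoint
#' ones. This is the primary gross-failure metric of the QA procedure.
#'
#' @param a,b [binary_mask()] objects on identical grids; at least one
#'   must be non-empty.
#' @return The Dice coefficient, a number in `[0, 1]`.
#' @export
#' @examples
#' g <- voxel_grid(c(0, 0, 0), c(1, 1, 2), c(4, 4, 1))
#' v <- array(FALSE, c(4, 4, 1)); v[1:2, , 1] <- TRUE
#' w <- array(FALSE, c(4, 4, 1)); w[2:3, , 1] <- TRUE
#' dsc_3d(binary_mask(g, v), binary_mask(g, w))  # 0.5
dsc_3d <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!same_grid(a$grid, b$grid)) {
    stop_segqa("masks are defined on different voxel grids", "segqa_geometry_error")
  }
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0L) {
    stop_segqa("both masks are empty; DSC is undefined", "segqa_undefined_metric_error")
  }
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Slice-wise 2D 95th-percentile Hausdorff distance
#'
#' Boundary-distance summary computed only on slices where both structures
#' have a contour. Each contour is resampled along its boundary at arc-length
#' steps of at most `sampling_step`; every sampled point's distance to the
#' other structure's full boundary polyline on the same slice is computed in
#' both directions; all distances from all shared slices are pooled and the
#' 95th percentile (linear interpolation between order statistics) is
#' returned. Slices with a contour in only one stack contribute nothing —
#' the reason superior-inferior truncation failures can evade this metric
#' while the 3D Dice coefficient still falls.
#'
#' @param gold,auto [contour_stack()] objects.
#' @param sampling_step Boundary resampling step, mm (> 0).
#' @param z_tol Slice-matching tolerance, mm; slices of the two stacks whose
#'   z differ by at most this are treated as the same plane. Default 1 mm,
#'   half the 2 mm CT slice thickness the pipeline assumes.
#' @param probs Percentile to report (default 0.95).
#' @return A list with `hd95` (mm, or `NA` when no shared slice exists),
#'   `n_shared`, `n_gold_only`, `n_auto_only`.
#' @export
hd95_2d <- function(gold, auto, sampling_step = 0.5, z_tol = 1, probs = 0.95) {
  stopifnot(inherits(gold, "contour_stack"), inherits(auto, "contour_stack"))
  if (!is_scalar_number(sampling_step) || sampling_step <= 0) {
    stop_segqa("'sampling_step' must be a positive number", "segqa_validation_error")
  }
  zg <- slice_z(gold); za <- slice_z(auto)
  if (!length(zg) || !length(za)) {
    stop_segqa("empty contour stack; distances are undefined",
               "segqa_undefined_metric_error")
  }
  # one-to-one nearest matching within tolerance
  match_a <- rep(NA_integer_, length(zg))
  taken <- logical(length(za))
  for (i in seq_along(zg)) {
    d <- abs(za - zg[i]); d[taken] <- Inf
    j <- which.min(d)
    if (d[j] <= z_tol) { match_a[i] <- j; taken[j] <- TRUE }
  }
  shared <- which(!is.na(match_a))
  n_shared <- length(shared)
  res <- list(hd95 = NA_real_, n_shared = n_shared,
              n_gold_only = length(zg) - n_shared,
              n_auto_only = length(za) - n_shared)
  if (n_shared == 0L) return(res)
  dists <- vector("list", 2L * n_shared)
  for (ii in seq_along(shared)) {
    pg <- gold$slices[[shared[ii]]]$polygons
    pa <- auto$slices[[match_a[shared[ii]]]]$polygons
    sg <- resample_polygons(pg, sampling_step)
    sa <- resample_polygons(pa, sampling_step)
    dists[[2L * ii - 1L]] <- dist_to_polylines(sg, pa)
    dists[[2L * ii]] <- dist_to_polylines(sa, pg)
  }
  res$hd95 <- as.numeric(stats::quantile(unlist(dists), probs = probs,
                                         type = 7, names = FALSE))
  res
}

# resample each closed polygon boundary at arc-length <= step, keeping the
# original vertices; returns one (n x 2) matrix of sample points
resample_polygons <- function(polys, step) {
  out <- lapply(polys, function(p) {
    n <- nrow(p)
    q <- p[c(seq_len(n)[-1], 1L), , drop = FALSE]
    seg <- sqrt(rowSums((q - p)^2))
    pieces <- pmax(1L, ceiling(seg / step))
    xs <- vector("list", n)
    for (k in seq_len(n)) {
      t <- (seq_len(pieces[k]) - 1L) / pieces[k]
      xs[[k]] <- cbind(p[k, 1] + t * (q[k, 1] - p[k, 1]),
                       p[k, 2] + t * (q[k, 2] - p[k, 2]))
    }
    do.call(rbind, xs)
  })
  do.call(rbind, out)
}

# minimum distance from each point to the union of closed polylines;
# vectorised as points x segments matrices
dist_to_polylines <- function(pts, polys) {
  px <- pts[, 1]; py <- pts[, 2]
  best <- rep(Inf, length(px))
  for (p in polys) {
    n <- nrow(p)
    nxt <- c(seq_len(n)[-1], 1L)
    ax <- p[, 1]; ay <- p[, 2]
    ex <- p[nxt, 1] - ax; ey <- p[nxt, 2] - ay
    L2 <- ex * ex + ey * ey
    L2[L2 == 0] <- 1  # degenerate segment: t collapses to the vertex anyway
    RX <- outer(px, ax, `-`); RY <- outer(py, ay, `-`)
    TT <- (RX * rep(ex, each = length(px)) + RY * rep(ey, each = length(px))) /
      rep(L2, each = length(px))
    TT[TT < 0] <- 0; TT[TT > 1] <- 1
    DX <- RX - TT * rep(ex, each = length(px))
    DY <- RY - TT * rep(ey, each = length(px))
    D2 <- DX * DX + DY * DY
    best <- pmin(best, do.call(pmin, as.data.frame(D2)))
  }
  sqrt(best)
}

#' Compare a gold/auto structure pair
#'
#' Runs both QA metrics on one [structure_pair()]: the 3D Dice coefficient
#' (after rasterizing both stacks onto a common grid) and the slice-wise 2D
#' 95% Hausdorff distance restricted to shared slices.
#'
#' @param pair A [structure_pair()].
#' @param grid Optional [voxel_grid()]; by default a grid covering both
#'   stacks is fitted with [fit_grid()].
#' @param spacing In-plane pixel size passed to [fit_grid()] when `grid` is
#'   missing.
#' @param sampling_step,z_tol Passed to [hd95_2d()].
#' @return A one-row data frame with columns `patient_id`, `organ`, `dsc`,
#'   `hd95_2d` (`NA` when no shared slice), `n_shared_slices`,
#'   `n_gold_only_slices`, `n_auto_only_slices`.
#' @export
compare_pair <- function(pair, grid = NULL, spacing = c(1, 1),
                         sampling_step = 0.5, z_tol = 1) {
  stopifnot(inherits(pair, "structure_pair"))
  if (is.null(grid)) grid <- fit_grid(pair$gold, pair$auto, spacing = spacing)
  dsc <- dsc_3d(rasterize(pair$gold, grid), rasterize(pair$auto, grid))
  hd <- hd95_2d(pair$gold, pair$auto, sampling_step = sampling_step, z_tol = z_tol)
  data.frame(patient_id = pair$patient_id, organ = pair$organ,
             dsc = dsc, hd95_2d = hd$hd95,
             n_shared_slices = hd$n_shared,
             n_gold_only_slices = hd$n_gold_only,
             n_auto_only_slices = hd$n_auto_only,
             stringsAsFactors = FALSE)
}

#' Write / read metric results as CSV
#'
#' The CSV carries one row per patient-organ comparison; an undefined
#' `hd95_2d` (no shared slice) is stored as an empty field.
#'
#' @param metrics Data frame as returned by [compare_pair()] (rows bound).
#' @param path File path.
#' @return `write_metrics_csv()` returns `path` invisibly;
#'   `read_metrics_csv()` returns the data frame.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(patient_id = "character", organ = "character"))
}
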