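#' Even-odd point-in-polygon test
#'
#' Tests each query point against one closed polygon with the even-odd
#' (parity) rule. Points lying on the polygon boundary (within `eps` mm)
#' count as inside — the fixed tie-break used throughout rasterization so
#' voxel membership is deterministic.
#'
#' @param px,py Numeric vectors of query point coordinates, mm.
#' @param poly Numeric n x 2 matrix of polygon vertices (implicitly closed).
#' @param eps Boundary tolerance in mm.
#' @return Logical vector, `TRUE` where the point is inside or on the boundary.
#' @export
points_in_polygon <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  nxt <- c(seq_len(n)[-1], 1L)
  x2 <- poly[nxt, 1]; y2 <- poly[nxt, 2]
  inside <- logical(length(px))
  on_b <- logical(length(px))
  eps2 <- eps * eps
  for (k in seq_len(n)) {
    dx <- x2[k] - x1[k]; dy <- y2[k] - y1[k]
    L2 <- dx * dx + dy * dy
    rx <- px - x1[k]; ry <- py - y1[k]
    # near-boundary candidates: perpendicular distance <= eps, then check
    # the projection falls on the segment (both tests exact at eps scale)
    cross <- rx * dy - ry * dx
    near <- which(cross * cross <= eps2 * L2)
    if (length(near)) {
      if (L2 > 0) {
        t <- (rx[near] * dx + ry[near] * dy) / L2
        t <- pmin(1, pmax(0, t))
        ddx <- rx[near] - t * dx; ddy <- ry[near] - t * dy
      } else {
        ddx <- rx[near]; ddy <- ry[near]
      }
      on_b[near[ddx * ddx + ddy * ddy <= eps2]] <- TRUE
    }
    crosses <- which((y1[k] > py) != (y2[k] > py))
    if (length(crosses)) {
      xint <- x1[k] + (py[crosses] - y1[k]) / dy * dx
      hit <- crosses[px[crosses] < xint]
      inside[hit] <- !inside[hit]
    }
  }
  inside | on_b
}

# even-odd membership across several polygons on one slice:
# parity of per-polygon interior tests; on any boundary counts as inside
points_in_polygons <- function(px, py, polys, eps = 1e-9) {
  inside <- logical(length(px))
  for (p in polys) inside <- xor(inside, points_in_polygon(px, py, p, eps))
  inside
}

#' Binary voxel mask
#'
#' @param grid A [voxel_grid()].
#' @param voxels Logical array with dimensions `grid$dim`, ordered (x, y, z).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(grid, voxels) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.logical(voxels) || !identical(dim(voxels), as.integer(grid$dim))) {
    stop_segqa("voxels must be a logical array matching grid dim",
               "segqa_validation_error")
  }
  structure(list(grid = grid, voxels = voxels), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d x %d, %d set voxel(s), voxel volume %g mm^3\n",
              x$grid$dim[1], x$grid$dim[2], x$grid$dim[3],
              sum(x$voxels), prod(x$grid$spacing)))
  invisible(x)
}

#' Rasterize a contour stack onto a voxel grid
#'
#' Converts planar polygons to a voxel occupancy mask. A voxel is set iff
#' its centre lies inside an odd number of the slice's polygons (even-odd
#' rule; centres on a polygon boundary count as inside). Every slice of the
#' stack must map to a grid z plane within half a slice thickness, and every
#' polygon must lie within the grid's xy extent.
#'
#' @param stack A [contour_stack()].
#' @param grid A [voxel_grid()].
#' @return A [binary_mask()].
#' @seealso [trace_mask()] for the inverse operation.
#' @export
#' @examples
#' sq <- cbind(c(-5, 5, 5, -5), c(-5, -5, 5, 5)) + 0.5
#' cs <- contour_stack("x", list(list(z = 0, polygons = list(sq))))
#' g <- voxel_grid(c(-9, -9, 0), c(1, 1, 2), c(20, 20, 1))
#' sum(rasterize(cs, g)$voxels)  # 100 pixel centres inside a 10 mm square
rasterize <- function(stack, grid) {
  stopifnot(inherits(stack, "contour_stack"), inherits(grid, "voxel_grid"))
  vox <- array(FALSE, dim = grid$dim)
  planes <- grid_z_planes(grid)
  dz <- grid$spacing[3]
  xs <- grid$origin[1] + (seq_len(grid$dim[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(grid$dim[2]) - 1) * grid$spacing[2]
  x_lo <- xs[1] - grid$spacing[1] / 2; x_hi <- xs[grid$dim[1]] + grid$spacing[1] / 2
  y_lo <- ys[1] - grid$spacing[2] / 2; y_hi <- ys[grid$dim[2]] + grid$spacing[2] / 2
  for (sl in stack$slices) {
    k <- which.min(abs(planes - sl$z))
    if (abs(planes[k] - sl$z) > dz / 2) {
      stop_segqa(sprintf("slice z = %g mm does not align with any grid plane (dz/2 = %g mm)",
                         sl$z, dz / 2), "segqa_alignment_error")
    }
    bb <- do.call(rbind, sl$polygons)
    if (min(bb[, 1]) < x_lo || max(bb[, 1]) > x_hi ||
        min(bb[, 2]) < y_lo || max(bb[, 2]) > y_hi) {
      stop_segqa("polygon extends beyond the grid's xy extent", "segqa_extent_error")
    }
    vox[, , k] <- vox[, , k] | fill_slice(sl$polygons, xs, ys)
  }
  binary_mask(grid, vox)
}

# Scanline even-odd fill of one slice: for each pixel row, pool the x
# intersections of all polygon edges with the row's y and set pixels with an
# odd number of intersections to their right (identical parity convention to
# points_in_polygon). A second pass marks pixel centres lying within eps of
# any edge as inside (the on-boundary rule).
fill_slice <- function(polys, xs, ys, eps = 1e-9) {
  x1 <- numeric(); y1 <- numeric(); x2 <- numeric(); y2 <- numeric()
  for (p in polys) {
    n <- nrow(p)
    nxt <- c(seq_len(n)[-1], 1L)
    x1 <- c(x1, p[, 1]); y1 <- c(y1, p[, 2])
    x2 <- c(x2, p[nxt, 1]); y2 <- c(y2, p[nxt, 2])
  }
  out <- matrix(FALSE, length(xs), length(ys))
  ylo <- min(pmin(y1, y2)); yhi <- max(pmax(y1, y2))
  rows <- which(ys >= ylo - eps & ys <= yhi + eps)
  dxdy <- (x2 - x1) / (y2 - y1)  # Inf/NaN on horizontal edges, never selected
  for (j in rows) {
    py <- ys[j]
    sel <- (y1 > py) != (y2 > py)
    if (!any(sel)) next
    xint <- sort.int(x1[sel] + (py - y1[sel]) * dxdy[sel], method = "quick")
    # pixel inside iff count of intersections strictly to its right is odd
    out[, j] <- (length(xint) - findInterval(xs, xint)) %% 2L == 1L
  }
  # boundary pass: a centre within eps of a steep edge lies in a row the
  # edge spans and within ~eps of the edge's x at that row (symmetrically
  # for shallow edges and columns); enumerate those candidates vectorised
  # and keep the ones whose exact point-to-segment distance is <= eps
  x0 <- xs[1]; y0 <- ys[1]
  dx <- if (length(xs) > 1) xs[2] - xs[1] else 1
  dy <- if (length(ys) > 1) ys[2] - ys[1] else 1
  ex <- x2 - x1; ey <- y2 - y1
  mark_candidates <- function(k) {
    if (!length(k)) return()
    steep <- abs(ey[k[1]]) >= abs(ex[k[1]])  # k holds one orientation class
    if (steep) {
      lo <- pmin(y1[k], y2[k]) - eps; hi <- pmax(y1[k], y2[k]) + eps
      j0 <- pmax(1, ceiling((lo - y0) / dy + 1)); j1 <- pmin(length(ys), floor((hi - y0) / dy + 1))
    } else {
      lo <- pmin(x1[k], x2[k]) - eps; hi <- pmax(x1[k], x2[k]) + eps
      j0 <- pmax(1, ceiling((lo - x0) / dx + 1)); j1 <- pmin(length(xs), floor((hi - x0) / dx + 1))
    }
    cnt <- pmax(0, j1 - j0 + 1)
    if (sum(cnt) == 0) return()
    eidx <- rep(k, cnt)
    jidx <- sequence(cnt) + rep(j0 - 1, cnt)
    if (steep) {
      t <- (ys[jidx] - y1[eidx]) / ey[eidx]
      t <- pmin(1, pmax(0, t))
      q <- x1[eidx] + t * ex[eidx]
      iidx <- round((q - x0) / dx) + 1
      ok <- iidx >= 1 & iidx <= length(xs)
      ci <- iidx[ok]; cj <- jidx[ok]
    } else {
      t <- (xs[jidx] - x1[eidx]) / ex[eidx]
      t <- pmin(1, pmax(0, t))
      q <- y1[eidx] + t * ey[eidx]
      cjj <- round((q - y0) / dy) + 1
      ok <- cjj >= 1 & cjj <= length(ys)
      ci <- jidx[ok]; cj <- cjj[ok]
    }
    if (!length(ci)) return()
    ke <- eidx[ok]
    tt <- pmin(1, pmax(0, ((xs[ci] - x1[ke]) * ex[ke] + (ys[cj] - y1[ke]) * ey[ke]) /
                           pmax(ex[ke]^2 + ey[ke]^2, 1e-300)))
    d2 <- (xs[ci] - x1[ke] - tt * ex[ke])^2 + (ys[cj] - y1[ke] - tt * ey[ke])^2
    hit <- d2 <= eps * eps
    if (any(hit)) out[cbind(ci[hit], cj[hit])] <<- TRUE
  }
  mark_candidates(which(abs(ey) >= abs(ex)))
  mark_candidates(which(abs(ey) < abs(ex)))
  out
}

#' Trace a binary mask back to planar contours
#'
#' Extracts, per axial slice, the closed loops of pixel-edge segments that
#' separate set from unset voxels. Loop vertices lie on voxel corners
#' (centre +/- spacing/2), so re-rasterizing the traced contours with the
#' pixel-centre rule reproduces the mask exactly.
#'
#' @param mask A [binary_mask()].
#' @param organ Organ label for the resulting stack.
#' @return A [contour_stack()] with one slice per non-empty mask plane.
#' @export
trace_mask <- function(mask, organ = "structure") {
  stopifnot(inherits(mask, "binary_mask"))
  g <- mask$grid
  planes <- grid_z_planes(g)
  slices <- list()
  for (k in seq_len(g$dim[3])) {
    m <- mask$voxels[, , k, drop = TRUE]
    dim(m) <- g$dim[1:2]
    if (!any(m)) next
    loops <- trace_plane(m)
    polys <- lapply(loops, function(lp) {
      cbind(g$origin[1] + (lp[, 1] - 1) * g$spacing[1],
            g$origin[2] + (lp[, 2] - 1) * g$spacing[2])
    })
    slices[[length(slices) + 1L]] <- list(z = planes[k], polygons = polys)
  }
  if (!length(slices)) {
    stop_segqa("mask is empty; nothing to trace", "segqa_validation_error")
  }
  contour_stack(organ, slices)
}

# Trace boundary loops of a binary 2D matrix. Returns loops in pixel-index
# coordinates where pixel (i, j) has centre (i, j) and corners at half
# integers. Directed boundary edges keep the inside on the left; any
# consistent chaining at corner crossings yields the same even-odd parity.
trace_plane <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  pad <- matrix(FALSE, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- m
  idx <- which(pad, arr.ind = TRUE)
  segs <- list()
  # for each set pixel, emit directed corner-to-corner edges against unset
  # neighbours; coordinates are corner lattice points (2x index to stay integer)
  i <- idx[, 1]; j <- idx[, 2]
  up <- !pad[cbind(i, j + 1)]; dn <- !pad[cbind(i, j - 1)]
  lf <- !pad[cbind(i - 1, j)]; rt <- !pad[cbind(i + 1, j)]
  # corner lattice: pixel (i,j) corners at (2i±1, 2j±1)
  add <- function(x1, y1, x2, y2) {
    if (length(x1)) segs[[length(segs) + 1L]] <<- cbind(x1, y1, x2, y2)
  }
  w <- which(dn); add(2 * i[w] - 1, 2 * j[w] - 1, 2 * i[w] + 1, 2 * j[w] - 1)  # bottom, ->
  w <- which(rt); add(2 * i[w] + 1, 2 * j[w] - 1, 2 * i[w] + 1, 2 * j[w] + 1)  # right, ^
  w <- which(up); add(2 * i[w] + 1, 2 * j[w] + 1, 2 * i[w] - 1, 2 * j[w] + 1)  # top, <-
  w <- which(lf); add(2 * i[w] - 1, 2 * j[w] + 1, 2 * i[w] - 1, 2 * j[w] - 1)  # left, v
  segs <- do.call(rbind, segs)
  key <- function(x, y) x * (2L * (ny + 2L) + 3L) + y
  from <- key(segs[, 1], segs[, 2])
  ord <- order(from)
  segs <- segs[ord, , drop = FALSE]
  from <- from[ord]
  first <- match(unique(from), from)
  lookup <- new.env(hash = TRUE, size = length(first))
  for (ii in seq_along(first)) {
    f <- first[ii]
    l <- if (ii < length(first)) first[ii + 1] - 1 else length(from)
    assign(as.character(from[f]), f:l, envir = lookup)
  }
  used <- logical(nrow(segs))
  loops <- list()
  for (s0 in seq_len(nrow(segs))) {
    if (used[s0]) next
    loop <- list()
    s <- s0
    repeat {
      used[s] <- TRUE
      loop[[length(loop) + 1L]] <- segs[s, 1:2]
      nk <- as.character(key(segs[s, 3], segs[s, 4]))
      cand <- get(nk, envir = lookup)
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      s <- cand[1]
    }
    pts <- do.call(rbind, loop)
    # drop collinear midpoints to keep polygons compact
    n <- nrow(pts)
    if (n >= 3) {
      prv <- rbind(pts[n, ], pts[-n, ])
      nxt <- rbind(pts[-1, ], pts[1, ])
      keep <- (nxt[, 1] - prv[, 1]) * (pts[, 2] - prv[, 2]) !=
              (pts[, 1] - prv[, 1]) * (nxt[, 2] - prv[, 2])
      pts <- pts[keep, , drop = FALSE]
    }
    # corner lattice -> unpadded pixel-index coordinates (half-integer corners)
    loops[[length(loops) + 1L]] <- pts / 2 - 1
  }
  loops
}
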