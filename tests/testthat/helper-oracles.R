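# Independent reference implementations used as oracles. Deliberately written
# as plain scalar loops / closed forms, sharing no code with the package
# internals they check.

# 95th-percentile Hausdorff by brute force: every sampled boundary point of
# one stack against every boundary segment of the other, scalar arithmetic,
# pooled over shared slices (nearest-z matching within z_tol).
brute_hd95 <- function(gold, auto, sampling_step = 0.5, z_tol = 1) {
  zg <- vapply(gold$slices, `[[`, numeric(1), "z")
  za <- vapply(auto$slices, `[[`, numeric(1), "z")
  dists <- numeric(0)
  taken <- logical(length(za))
  for (i in seq_along(zg)) {
    d <- abs(za - zg[i]); d[taken] <- Inf
    j <- which.min(d)
    if (d[j] > z_tol) next
    taken[j] <- TRUE
    pg <- gold$slices[[i]]$polygons
    pa <- auto$slices[[j]]$polygons
    sg <- brute_resample(pg, sampling_step)
    sa <- brute_resample(pa, sampling_step)
    for (r in seq_len(nrow(sg))) {
      dists <- c(dists, brute_point_dist(sg[r, 1], sg[r, 2], pa))
    }
    for (r in seq_len(nrow(sa))) {
      dists <- c(dists, brute_point_dist(sa[r, 1], sa[r, 2], pg))
    }
  }
  if (!length(dists)) return(NA_real_)
  as.numeric(stats::quantile(dists, 0.95, type = 7, names = FALSE))
}

brute_resample <- function(polys, step) {
  pts <- NULL
  for (p in polys) {
    n <- nrow(p)
    for (k in seq_len(n)) {
      a <- p[k, ]; b <- p[if (k == n) 1 else k + 1, ]
      len <- sqrt(sum((b - a)^2))
      m <- max(1, ceiling(len / step))
      for (s in seq_len(m) - 1) pts <- rbind(pts, a + (s / m) * (b - a))
    }
  }
  pts
}

brute_point_dist <- function(px, py, polys) {
  best <- Inf
  for (p in polys) {
    n <- nrow(p)
    for (k in seq_len(n)) {
      a <- p[k, ]; b <- p[if (k == n) 1 else k + 1, ]
      ex <- b[1] - a[1]; ey <- b[2] - a[2]
      L2 <- ex^2 + ey^2
      t <- if (L2 > 0) max(0, min(1, ((px - a[1]) * ex + (py - a[2]) * ey) / L2)) else 0
      d <- sqrt((px - a[1] - t * ex)^2 + (py - a[2] - t * ey)^2)
      if (d < best) best <- d
    }
  }
  best
}

# translate every vertex of a stack in-plane
translate_stack <- function(stack, dx = 0, dy = 0) {
  contour_stack(stack$organ, lapply(stack$slices, function(s) {
    s$polygons <- lapply(s$polygons, function(p) {
      cbind(p[, 1] + dx, p[, 2] + dy)
    })
    s
  }))
}

# shoelace polygon area
shoelace_area <- function(p) {
  n <- nrow(p)
  nxt <- c(seq_len(n)[-1], 1L)
  abs(sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2])) / 2
}

# analytic lower-tail probability of Normal(mean, sd) truncated to (0, 1]
trunc_normal_tail <- function(q, mean, sd, lower = 0, upper = 1) {
  (pnorm(q, mean, sd) - pnorm(lower, mean, sd)) /
    (pnorm(upper, mean, sd) - pnorm(lower, mean, sd))
}
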