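#' Default per-organ DSC statistics for head-and-neck OARs
#'
#' Published reference-cohort DSC statistics (mean ± SD over a 50-patient
#' gold-vs-auto comparison) for four routinely contoured head-and-neck
#' organs at risk. These are the default parameters of
#' [simulate_metric_cohort()]; the implied three-sigma gross-failure levels
#' are 0.63 (brainstem), 0.85 (mandible), 0.58 (left parotid) and 0.50
#' (right parotid).
#'
#' @return Data frame with columns `organ`, `dsc_mean`, `dsc_sd`,
#'   `n_reference`.
#' @export
oar_reference_defaults <- function() {
  data.frame(
    organ = c("brainstem", "mandible", "parotid_l", "parotid_r"),
    dsc_mean = c(0.81, 0.91, 0.76, 0.74),
    dsc_sd = c(0.06, 0.02, 0.06, 0.08),
    n_reference = 50L,
    stringsAsFactors = FALSE)
}

#' Generate a geometric organ phantom
#'
#' Builds a synthetic [contour_stack()] standing in for a head-and-neck
#' organ on a CT-like slice grid. Three archetypes are provided:
#' `"ellipsoid"` (brainstem/parotid-like; per-slice circles of radius
#' `a * sqrt(1 - ((z - z0)/c)^2)`), `"cylinder"` (constant circular
#' cross-section; the analytically tractable test shape), and
#' `"horseshoe"` (mandible-like C-shaped cross-section).
#'
#' @param archetype One of `"ellipsoid"`, `"cylinder"`, `"horseshoe"`.
#' @param organ Organ label.
#' @param center (x, y, z) centre, mm.
#' @param radius In-plane radius `a`, mm (outer radius for the horseshoe).
#' @param semi_z Superior-inferior semi-axis `c` for the ellipsoid, mm;
#'   defaults to half the stack height.
#' @param n_slices Number of axial slices (>= 1).
#' @param slice_thickness Slice spacing, mm (default 2, a typical
#'   planning-CT slice thickness).
#' @param n_vertices Vertices per contour polygon (>= 8).
#' @param inner_frac Horseshoe only: inner radius as a fraction of `radius`.
#' @param gap_angle Horseshoe only: angular opening of the "C", radians.
#' @return A [contour_stack()].
#' @details Deterministic: the same arguments always produce identical
#'   vertex lists. Ellipsoid slices are placed strictly inside the
#'   superior-inferior extent so every slice has a non-degenerate contour.
#' @export
#' @examples
#' cyl <- make_phantom("cylinder", radius = 10, n_slices = 20)
#' length(cyl$slices)
make_phantom <- function(archetype = c("ellipsoid", "cylinder", "horseshoe"),
                         organ = archetype, center = c(0, 0, 0),
                         radius = 15, semi_z = NULL, n_slices = 20,
                         slice_thickness = 2, n_vertices = 64,
                         inner_frac = 0.55, gap_angle = pi / 3) {
  archetype <- match.arg(archetype)
  organ <- organ[1]
  stopifnot(radius > 0, n_slices >= 1, slice_thickness > 0, n_vertices >= 8)
  height <- n_slices * slice_thickness
  if (is.null(semi_z)) semi_z <- height / 2
  # slice planes symmetric about center z, strictly inside the extent
  z_off <- (seq_len(n_slices) - (n_slices + 1) / 2) * slice_thickness
  theta <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  slices <- lapply(seq_len(n_slices), function(k) {
    z <- center[3] + z_off[k]
    r <- switch(archetype,
      cylinder = radius,
      ellipsoid = radius * sqrt(max(0, 1 - (z_off[k] / semi_z)^2)),
      horseshoe = radius)
    r <- max(r, 0.05 * radius)  # keep a valid polygon at the poles
    if (archetype == "horseshoe") {
      poly <- horseshoe_polygon(center[1:2], r, inner_frac * r, gap_angle,
                                n_vertices)
    } else {
      poly <- cbind(center[1] + r * cos(theta), center[2] + r * sin(theta))
    }
    list(z = z, polygons = list(poly))
  })
  contour_stack(organ, slices)
}

# C-shaped polygon: outer arc + inner arc traversed back, opening of
# 'gap_angle' radians centred on +y (the anterior gap of a mandible-like shape)
horseshoe_polygon <- function(center, r_out, r_in, gap_angle, n_vertices) {
  n_arc <- max(4L, floor(n_vertices / 2))
  a0 <- pi / 2 + gap_angle / 2
  a1 <- pi / 2 - gap_angle / 2 + 2 * pi
  ang <- seq(a0, a1, length.out = n_arc)
  outer <- cbind(center[1] + r_out * cos(ang), center[2] + r_out * sin(ang))
  inner <- cbind(center[1] + r_in * cos(rev(ang)), center[2] + r_in * sin(rev(ang)))
  rbind(outer, inner)
}

#' Apply a failure-mode perturbation to a contour stack
#'
#' Produces the auto-contour of a synthetic gold/auto pair by distorting a
#' phantom with one of four contour-level failure surrogates:
#'
#' * `"truncate_si"` — removes the `k` most superior (or inferior) slices,
#'   emulating artefact-induced superior-inferior truncation of the
#'   auto-contour (dental-artefact failures);
#' * `"roll"` — rotates every slice in-plane by `angle` degrees about
#'   `pivot`, emulating a non-standard patient setup roll (observed rolls
#'   are around 7 degrees about an axis away from the organ);
#' * `"attach_component"` — adds a disjoint circular component near the
#'   structure on a band of slices, emulating inclusion of non-organ
#'   material such as a surgical plate;
#' * `"boundary_noise"` — displaces every vertex radially (about the slice
#'   centroid) by seeded Gaussian noise, emulating ordinary delineation
#'   variability.
#'
#' @param stack A [contour_stack()].
#' @param kind Perturbation kind (see above).
#' @param k Slices to remove (`truncate_si`); must be < number of slices.
#' @param end `"superior"` (largest z) or `"inferior"`.
#' @param angle Roll angle, degrees.
#' @param pivot (x, y) rotation pivot, mm; defaults to the structure's
#'   centroid (a pure in-place roll).
#' @param blob_center (x, y) centre of the attached component, mm; defaults
#'   to 1.8x the mean radius lateral of the centroid.
#' @param blob_radius Radius of the attached component, mm.
#' @param blob_slices Indices of slices receiving the component (default:
#'   the middle 60%).
#' @param amplitude Gaussian radial noise SD, mm (`boundary_noise`).
#' @param seed Integer seed for `boundary_noise`; same seed, same output.
#' @return A perturbed [contour_stack()].
#' @export
#' @examples
#' cyl <- make_phantom("cylinder", radius = 10, n_slices = 20)
#' short <- perturb(cyl, "truncate_si", k = 5)
#' length(short$slices)
perturb <- function(stack, kind = c("truncate_si", "roll", "attach_component",
                                    "boundary_noise"),
                    k = 1, end = c("superior", "inferior"),
                    angle = 7, pivot = NULL,
                    blob_center = NULL, blob_radius = NULL, blob_slices = NULL,
                    amplitude = 0.5, seed = NULL) {
  stopifnot(inherits(stack, "contour_stack"))
  kind <- match.arg(kind)
  n <- length(stack$slices)
  switch(kind,
    truncate_si = {
      end <- match.arg(end)
      if (k >= n) {
        stop_segqa(sprintf("cannot remove %d of %d slices", k, n),
                   "segqa_degenerate_structure_error")
      }
      keep <- if (end == "superior") seq_len(n - k) else (k + 1):n
      contour_stack(stack$organ, stack$slices[keep])
    },
    roll = {
      ctr <- stack_centroid(stack)
      if (is.null(pivot)) pivot <- ctr[1:2]
      a <- angle * pi / 180
      R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
      contour_stack(stack$organ, lapply(stack$slices, function(s) {
        s$polygons <- lapply(s$polygons, function(p) {
          sweep(sweep(p, 2, pivot) %*% t(R), 2, pivot, `+`)
        })
        s
      }))
    },
    attach_component = {
      ctr <- stack_centroid(stack)
      rad <- mean_radius(stack)
      if (is.null(blob_center)) blob_center <- ctr[1:2] + c(1.8 * rad, 0)
      if (is.null(blob_radius)) blob_radius <- 0.5 * rad
      if (is.null(blob_slices)) {
        blob_slices <- seq(max(1L, ceiling(0.2 * n)), floor(0.8 * n))
      }
      theta <- 2 * pi * (seq_len(32) - 1) / 32
      blob <- cbind(blob_center[1] + blob_radius * cos(theta),
                    blob_center[2] + blob_radius * sin(theta))
      slices <- stack$slices
      for (i in blob_slices) {
        slices[[i]]$polygons <- c(slices[[i]]$polygons, list(blob))
      }
      contour_stack(stack$organ, slices)
    },
    boundary_noise = {
      with_seed(seed, {
        contour_stack(stack$organ, lapply(stack$slices, function(s) {
          cen <- colMeans(do.call(rbind, s$polygons))
          s$polygons <- lapply(s$polygons, function(p) {
            d <- sweep(p, 2, cen)
            r <- sqrt(rowSums(d^2))
            r_new <- pmax(0.05 * mean(r), r + stats::rnorm(nrow(p), 0, amplitude))
            sweep(d * (r_new / pmax(r, 1e-12)), 2, cen, `+`)
          })
          s
        }))
      })
    })
}

stack_centroid <- function(stack) {
  pts <- do.call(rbind, unlist(lapply(stack$slices, `[[`, "polygons"),
                               recursive = FALSE))
  c(colMeans(pts), mean(slice_z(stack)))
}

mean_radius <- function(stack) {
  ctr <- stack_centroid(stack)
  pts <- do.call(rbind, unlist(lapply(stack$slices, `[[`, "polygons"),
                               recursive = FALSE))
  mean(sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2))
}

#' Simulate per-organ DSC cohorts at the metric level
#'
#' Draws a cohort of DSC values directly at the metric level (no geometry):
#' in-control values come from a Normal(`dsc_mean`, `dsc_sd`) truncated to
#' `(0, 1]`; with probability `gross_failure_prob` a value is replaced by a
#' gross failure drawn uniformly from `failure_dsc_range`. Ground-truth
#' failure labels are retained so detection performance can be scored.
#'
#' @param params Data frame with columns `organ`, `dsc_mean`, `dsc_sd` and
#'   optionally `n_patients`, `gross_failure_prob`, `failure_dsc_lo`,
#'   `failure_dsc_hi` (defaults: [oar_reference_defaults()] with
#'   `n_patients`, `gross_failure_prob` and the failure range below).
#' @param n_patients,gross_failure_prob,failure_dsc_range Defaults applied
#'   to organs missing those columns. The default failure range
#'   `(0.1, 0.4)` lies well below every default three-sigma limit.
#' @param seed Integer seed; the caller's RNG state is restored.
#' @return Data frame with columns `organ`, `patient_id`, `dsc`,
#'   `is_failure` (logical ground truth).
#' @export
#' @examples
#' coh <- simulate_metric_cohort(n_patients = 100, seed = 1)
#' table(coh$organ, coh$is_failure)
simulate_metric_cohort <- function(params = oar_reference_defaults(),
                                   n_patients = 500,
                                   gross_failure_prob = 0.012,
                                   failure_dsc_range = c(0.1, 0.4),
                                   seed = NULL) {
  if (!all(c("organ", "dsc_mean", "dsc_sd") %in% names(params))) {
    stop_segqa("'params' needs organ, dsc_mean, dsc_sd", "segqa_validation_error")
  }
  if (!"n_patients" %in% names(params)) params$n_patients <- n_patients
  if (!"gross_failure_prob" %in% names(params)) {
    params$gross_failure_prob <- gross_failure_prob
  }
  if (!"failure_dsc_lo" %in% names(params)) params$failure_dsc_lo <- failure_dsc_range[1]
  if (!"failure_dsc_hi" %in% names(params)) params$failure_dsc_hi <- failure_dsc_range[2]
  if (any(params$gross_failure_prob < 0 | params$gross_failure_prob > 1)) {
    stop_segqa("gross_failure_prob must lie in [0, 1]", "segqa_validation_error")
  }
  if (any(params$failure_dsc_hi >= params$dsc_mean - 3 * params$dsc_sd)) {
    stop_segqa("failure_dsc_range must lie below dsc_mean - 3 * dsc_sd",
               "segqa_validation_error")
  }
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(params)), function(i) {
      p <- params[i, ]
      n <- p$n_patients
      dsc <- rnorm_truncated(n, p$dsc_mean, p$dsc_sd)
      fail <- stats::runif(n) < p$gross_failure_prob
      dsc[fail] <- stats::runif(sum(fail), p$failure_dsc_lo, p$failure_dsc_hi)
      data.frame(organ = p$organ,
                 patient_id = sprintf("%s_%04d", p$organ, seq_len(n)),
                 dsc = dsc, is_failure = fail, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

# archetype and geometry used for each default organ phantom
organ_archetypes <- function() {
  data.frame(
    organ = c("brainstem", "mandible", "parotid_l", "parotid_r"),
    archetype = c("ellipsoid", "horseshoe", "ellipsoid", "ellipsoid"),
    radius = c(12, 45, 20, 20),
    n_slices = c(16, 14, 16, 16),
    cx = c(0, 0, -55, 55), cy = c(40, 0, 30, 30),
    stringsAsFactors = FALSE)
}

#' Simulate a cohort of gold/auto contour phantom pairs
#'
#' Generates the full geometric input of a QA run without patient data: for
#' each patient and organ, a gold-standard phantom and an auto phantom. The
#' auto contour of a normal comparison differs from gold by radial boundary
#' noise whose amplitude varies from patient to patient (ordinary
#' delineation variability); with probability `failure_prob` a gross
#' failure perturbation is injected on top, drawn uniformly from the three
#' observed archetypes — superior-inferior truncation (40-60% of slices),
#' a 7-degree setup roll about a pivot 40 mm from the organ, or attachment
#' of a disjoint component. The injected kind is recorded in the manifest
#' so end-to-end recovery can be checked and review annotations derived.
#'
#' @param n_patients Number of patients.
#' @param organs Organ subset of [organ_archetypes()] (default all four).
#' @param failure_prob Probability a pair carries an injected gross failure.
#' @param noise_range Range (mm) the per-patient boundary-noise SD is drawn
#'   from, uniformly.
#' @param seed Integer seed; deterministic output for a given seed.
#' @return A list of class `phantom_cohort`: `pairs` (list of
#'   [structure_pair()]) and `manifest` (data frame: `patient_id`, `organ`,
#'   `injected` kind or `"none"`, `parameter` value, `noise_sd`, `seed`).
#' @export
#' @examples
#' coh <- simulate_contour_cohort(n_patients = 2, organs = "brainstem", seed = 1)
#' coh$manifest
simulate_contour_cohort <- function(n_patients, organs = organ_archetypes()$organ,
                                    failure_prob = 0, noise_range = c(0.3, 1.2),
                                    seed = 1) {
  arch <- organ_archetypes()
  arch <- arch[arch$organ %in% organs, , drop = FALSE]
  if (!nrow(arch)) stop_segqa("no known organs requested", "segqa_validation_error")
  pairs <- list()
  manifest <- list()
  with_seed(seed, {
    for (oi in seq_len(nrow(arch))) {
      a <- arch[oi, ]
      gold <- make_phantom(a$archetype, organ = a$organ,
                           center = c(a$cx, a$cy, 0), radius = a$radius,
                           n_slices = a$n_slices)
      for (p in seq_len(n_patients)) {
        pid <- sprintf("pt%04d", p)
        sub_seed <- sample.int(.Machine$integer.max, 1)
        noise_sd <- stats::runif(1, noise_range[1], noise_range[2])
        auto <- perturb(gold, "boundary_noise", amplitude = noise_sd,
                        seed = sub_seed)
        injected <- "none"; param <- NA_real_
        if (stats::runif(1) < failure_prob) {
          injected <- sample(c("truncate_si", "roll", "attach_component"), 1)
          if (injected == "truncate_si") {
            param <- round(stats::runif(1, 0.4, 0.6) * a$n_slices)
            auto <- perturb(auto, "truncate_si", k = param)
          } else if (injected == "roll") {
            param <- 7
            auto <- perturb(auto, "roll", angle = param,
                            pivot = c(a$cx, a$cy - 40))
          } else {
            param <- 0.6 * a$radius
            auto <- perturb(auto, "attach_component", blob_radius = param)
          }
        }
        pairs[[length(pairs) + 1L]] <- structure_pair(pid, gold, auto)
        manifest[[length(manifest) + 1L]] <- data.frame(
          patient_id = pid, organ = a$organ, injected = injected,
          parameter = param, noise_sd = noise_sd, seed = sub_seed,
          stringsAsFactors = FALSE)
      }
    }
  })
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  structure(list(pairs = pairs, manifest = manifest), class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d pair(s), %d organ(s), %d injected failure(s)\n",
              nrow(x$manifest), length(unique(x$manifest$organ)),
              sum(x$manifest$injected != "none")))
  invisible(x)
}

#' Derive review annotations from a cohort manifest
#'
#' Maps each injected perturbation kind to the review verdict an expert
#' would assign to its real-world counterpart: setup roll -> `setup`,
#' attached component -> `anatomy`, superior-inferior truncation ->
#' `artefacts`. Used to close the loop in synthetic end-to-end runs; real
#' audits take human-written annotation CSVs instead.
#'
#' @param manifest Manifest from [simulate_contour_cohort()].
#' @param flags Optional flagged results; when given, annotations are also
#'   produced (verdict `"unknown"`) for flagged pairs with no injection, so
#'   the review is complete even if ordinary variability trips a limit.
#' @return Annotation data frame for [apply_review()].
#' @export
annotations_from_manifest <- function(manifest, flags = NULL) {
  map <- c(roll = "setup", attach_component = "anatomy",
           truncate_si = "artefacts")
  inj <- manifest[manifest$injected != "none", , drop = FALSE]
  ann <- data.frame(patient_id = inj$patient_id, organ = inj$organ,
                    verdict = unname(map[inj$injected]),
                    note = paste0("injected:", inj$injected),
                    stringsAsFactors = FALSE)
  if (!is.null(flags)) {
    fl <- flags[flags$dsc_failed, c("patient_id", "organ"), drop = FALSE]
    key <- paste(ann$patient_id, ann$organ)
    extra <- fl[!paste(fl$patient_id, fl$organ) %in% key, , drop = FALSE]
    if (nrow(extra)) {
      ann <- rbind(ann, data.frame(patient_id = extra$patient_id,
                                   organ = extra$organ, verdict = "unknown",
                                   note = "no injected cause",
                                   stringsAsFactors = FALSE))
    }
    # keep only annotations that match a flagged pair
    fkey <- paste(fl$patient_id, fl$organ)
    ann <- ann[paste(ann$patient_id, ann$organ) %in% fkey, , drop = FALSE]
  }
  rownames(ann) <- NULL
  ann
}
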