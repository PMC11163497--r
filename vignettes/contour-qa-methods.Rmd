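---
title: "Statistical QA of auto-segmented organ contours: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical QA of auto-segmented organ contours: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segqa)
```

## The problem

Deep-learning systems now delineate radiotherapy organs at risk (OARs)
automatically, but they fail occasionally and in characteristic ways:
a non-standard patient setup (for instance an axial roll of several
degrees), unusual internal anatomy such as post-surgical hardware, or CT
artefacts from dental fillings can each produce a grossly wrong contour.
Routine clinical practice therefore still relies on a human inspecting
every contour. `segqa` implements the statistical alternative: learn what
*normal* agreement between expert and automatic contours looks like on a
reference cohort, set an action limit, and audit new cases against it so
that attention concentrates on the rare gross failures.

## The two metrics

**3D Dice similarity coefficient.** For voxelized structures $A$ (gold
standard) and $B$ (auto), $\mathrm{DSC} = 2|A\cap B| / (|A| + |B|)$: 1 for
identical structures, 0 for disjoint ones. This is the primary QA
statistic. We compute it voxel-wise: contours are rasterized onto a
common grid and the ratio is taken over voxel counts. A mesh-based volume
overlap would differ only at the discretization scale; the voxel route is
chosen because it is exactly reproducible and oracle-checkable (the count
of pixel centres inside a polygon is a well-defined integer).

**Slice-wise 2D 95% Hausdorff distance.** Planar contours live on CT
slices, so boundary distances are computed per axial slice, and only on
slices where *both* structures have a contour. Each boundary is resampled
at arc-length steps of at most `sampling_step` (default 0.5 mm); each
sampled point contributes its distance to the other structure's full
boundary polyline (segment-accurate, not vertex-to-vertex, to avoid
sampling artifacts); distances from both directions and all shared slices
are pooled, and the 95th percentile is taken with linear interpolation
between order statistics (R's default quantile type 7), which makes
results bit-stable across runs.

Two conventions here are genuinely open choices and are worth stating
plainly. First, there is no canonical way to aggregate per-slice Hausdorff
values into one number per organ; we pool *all* directed point distances
across shared slices and take a single 95th percentile. Pooling is robust,
reduces to the per-slice value for single-slice structures, and weights
slices by their boundary length. Second, slices present in only one stack
are excluded (and counted in the output) rather than assigned an infinite
or penalty distance. That exclusion is exactly why the metric can be blind
to superior–inferior truncation failures: a structure cut short by dental
artefacts has identical cross-sections on every shared slice, so its HD95
is 0 mm while its DSC drops by the closed form $2(N-k)/(2N-k)$ for $k$ of
$N$ uniform slices removed. The package reproduces this mechanism as a
property test; it is the reason DSC, not HD95, drives failure flagging.

## Geometry conventions

Coordinates are patient-space millimetres, x/y in-plane, z
superior–inferior; contours are closed planar polygons on axial slices,
implicitly closed, with multi-polygon slices supported (a mandible's two
rami, or an artefact-split organ). Rasterization uses pixel-centre
membership under the even-odd rule, with centres lying exactly on a
polygon boundary counting as inside — a deterministic tie-break that a
brute-force ray-casting oracle can verify. The default grid spacing is
1 × 1 mm in-plane (a representative head-and-neck CT pixel; configurable)
with 2 mm slices, and slice z positions must match grid planes within half
a slice thickness. Masks trace back to contours along voxel-edge loops
(vertices at half-pixel corners), which makes rasterize → trace →
rasterize exactly idempotent; any consistent chaining of boundary edges at
corner-touching pixels yields the same even-odd parity, so the tracer's
loop pairing is not a correctness concern.

## The three-sigma limit model

Per organ, the reference cohort's DSC values give a mean $\mu$ and sample
standard deviation $s$ (denominator $n-1$; with $n = 50$ the difference
from $n$ is far below the printed precision). The gross-failure limit is

$$L = \mu - 3s,$$

clamped at 0, with a result flagged when $\mathrm{DSC} < L$ strictly — a
value exactly at the limit is in control, matching the reading of failures
as results *below* the level. When HD95 values are supplied an upper limit
$\mu_{HD} + 3s_{HD}$ is fitted symmetrically, but HD flags are reported
only; the failure accounting is DSC-driven. Limits are one-sided because
an unusually *high* DSC or low HD is not a failure mode. Limits are
carried at full precision and rounded (half-up) only for display.

Under normality about 0.135% of in-control results fall below a one-sided
three-sigma limit. The package's DSC simulator draws from a normal
truncated to $(0, 1]$ — normality is inherited from the three-sigma rule
itself, which presumes roughly 99.7% of in-control results within the
limits; no distributional diagnostics for real cohorts are implied.
For the default organ parameters the truncation correction is negligible
(the upper bound sits more than 3 standard deviations above every default
mean).

A known numerical footnote: for the right-parotid default (mean 0.74,
SD 0.08) the full-precision limit is 0.50, while the published table from
which these defaults are taken prints 0.51 — consistent with the table's
mean/SD themselves being rounded before the limit was formed. The package
reports 0.50 and does not attempt to match the printed value.

A statistical caveat the package's tests document honestly: the estimator
$\hat\mu - 3\hat s$ at $n = 50$ has standard deviation
$\sigma\sqrt{1/n + 9/(2(n-1))} \approx 0.33\sigma$, so only about 87% of
calibration runs land within $\pm 0.5\sigma$ of the true limit. A
coverage target of 95% at that tolerance is not attainable at $n = 50$;
reaching it would need roughly $n \ge 90$.

## Review and reporting

Expert review is an explicit *input*, never automated: every DSC-flagged
comparison must carry exactly one annotation, either censoring it (the
manual contour, not the AI contour, was suboptimal) or assigning one of
four failure modes — setup, anatomy, artefacts, unknown. The bookkeeping
is enforced (missing or duplicate annotations are errors), and censoring
removes a record from the true-failure numerator but *not* from the
evaluated denominator: with 500 evaluations per organ, 20 flags and 9
censored, the true-failure rate is 11/500 = 2.2%. Rates are reported as
percentages at one decimal place, rounding ties up. The pooled outputs
are the overall true-failure rate (total true failures over total
evaluations) and the censored fraction of all flags.

## The synthetic cohort model

No patient data ships with the package; a generator emulates gold/auto
contour pairs on a CT-like grid (2 mm slices) for four organ archetypes:
ellipsoids for brainstem (radius 12 mm) and parotids (20 mm), a C-shaped
horseshoe for the mandible (outer radius 45 mm), plus a cylinder used in
analytic tests. Ordinary delineation variability is modeled as radial
Gaussian vertex noise whose per-patient amplitude is drawn uniformly from
0.3–1.2 mm. Drawing the *amplitude* per patient is deliberate: it gives
the cohort's DSC distribution a bounded, roughly uniform spread, so the
fitted $\mu - 3s$ limit sits strictly below the attainable in-control
minimum (for a uniform distribution the mean minus three SDs lies below
the support's lower edge). End-to-end failure-count recovery is then
exact by design rather than merely probable — a property chosen for the
generator as the package's test harness, and a respect in which the
synthetic cohort is *easier* than real data, where the in-control tail is
unbounded and ~0.135% false flags are expected and handled by review.

Injected gross failures reproduce the three observed archetypes at
severities characteristic of real gross failures: superior–inferior
truncation removing 40–60% of slices (the dental-artefact mechanism), a
7° in-plane roll about a pivot 40 mm from the organ (a setup-roll
surrogate; the displacement, not the angle alone, is what matters, hence
the distant pivot), and attachment of a disjoint component of 0.6× the
organ radius (the surgical-plate surrogate). All three depress DSC well
below every fitted limit under the noise model above. The generator
records every injection in a manifest, from which review annotations are
derived mechanically (roll → setup, attached component → anatomy,
truncation → artefacts) to close the loop in end-to-end tests; real
audits take human-written annotation files instead.

What the phantoms do *not* model: image content (artefacts and plates act
only through their contour-level consequences), inter-observer
variability structure, organ-shape statistics, or any correlation between
organs of one patient. Passing end-to-end tests therefore demonstrates
the pipeline's bookkeeping and metrics are correct, not that real failure
rates will match.

## Problem sizes and determinism

The test suite and acceptance script size their simulations as follows:
the Monte-Carlo check of the in-control flagged fraction uses $10^6$
metric-level draws (standard error $\approx 4\times10^{-5}$ on a tail of
$1.35\times10^{-3}$); limit-recovery sampling uses 1000 replicates of 50
draws; the end-to-end audit uses the study design of 50 reference and 500
audit pairs per organ across all four archetypes. Every stochastic stage
takes an explicit integer seed, callers' RNG state is restored, and each
generated cohort's manifest records the sub-seed of every pair, so every
figure the package produces is exactly reproducible from its provenance
record.

## Known limitations

* Only axis-aligned geometries: no non-axial contours, no rotated NIfTI
  affines, no image registration.
* DICOM-RT support covers explicit-VR little-endian structure sets with
  CLOSED_PLANAR contours — the common interchange case — not the full
  standard.
* The HD95 aggregation convention (pooled percentile over shared slices)
  is one of several defensible choices; comparisons with tools that
  aggregate per-slice maxima will differ.
* Published per-organ HD thresholds (e.g. 11.6 mm for brainstem) cannot
  be re-derived without the underlying patient data; the package fits HD
  limits from whatever reference HD values it is given.
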