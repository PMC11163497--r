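Package: segqa
Title: Quality Assurance for AI-Based Organ-at-Risk Auto-Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical quality assurance for automatically generated
    radiotherapy organ-at-risk contours. Computes 3D Dice similarity
    coefficients and slice-wise 2D 95th-percentile Hausdorff distances
    between gold-standard and auto-generated contours, fits per-organ
    three-sigma gross-failure limits from a reference cohort, flags and
    censors failures in an audit cohort, classifies reviewed failure
    modes, and reports per-organ true-failure rates. Includes a synthetic
    contour-phantom generator emulating head-and-neck organ pairs on a
    CT-like slice grid, with controlled failure-mode perturbations, and
    readers for DICOM-RT structure sets, a planar contour JSON format,
    and NIfTI binary masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    RNifti,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
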