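Package: fmriqc
Title: Quality Control Metrics, Artifact Detectors and Reports for FMRI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-subject quality-control metrics and artifact detectors for
    4D echo-planar imaging (EPI) time series: motion Euclidean-norm and
    outlier-fraction censoring, temporal signal-to-noise ratio (TSNR) maps,
    global correlation (GCOR), whole-brain residual correlation, radial
    correlation, carpet (grayplot) matrices, degrees-of-freedom accounting
    for regression models, left-right flip detection via a local Pearson
    correlation cost, through-plane variance-line detection, per-ROI TSNR
    and shape tables, a self-contained static HTML QC report with persisted
    ratings and comments, cross-subject tabulation and filtering of review
    quantities, and a deterministic synthetic phantom generator that plants
    each artifact class with a ground-truth record so every detector is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    tibble,
    png,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
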