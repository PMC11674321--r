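Package: hubdisrupt
Title: Normalized Hub Disruption Analysis of Functional Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying selective hub vulnerability in weighted
    functional connectivity networks. Implements signed, asymmetrically
    weighted nodal centrality metrics (strength, participation coefficient,
    within-module strength Z-score), maximum-spanning-tree backbone density
    thresholding, the normalized hub disruption index (percentage change in
    centrality regressed on reference hub rank) together with the legacy
    absolute-difference index, targeted/random/non-hub attack simulations, a
    synthetic staged-cohort generator with biomarker trajectories, group-level
    statistics (matching, ROI-wise tests with false discovery rate control,
    mixed-model cognition regression, binned AUC), and penalized-spline
    trajectory fits with simultaneous confidence bands for divergence-point
    estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mgcv,
    withr
Config/testthat/edition: 3
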