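Package: groupmotion
Title: Quantitative Analysis of Spontaneous Social Movement in Free-Running Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify spontaneous social movement in bounded-arena
    group activity from 2-D position time series. Provides trajectory ingestion
    (projective floor calibration, spline resampling to a uniform frame grid,
    velocity estimation), collective-motion indices (pairwise distance, heading
    angle toward a partner, per-individual angular momentum about the static
    group centre), approach-event detection with look-back approaching-angle
    sampling, per-individual normalized-histogram group comparison (pooled
    two-sample t-tests with Bonferroni correction and Hedges' g), directed-pair
    approach matrices, and an agent-based generator of rotation-like and
    pursuit ("tag") trajectories for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
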