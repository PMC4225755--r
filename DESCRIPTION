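Package: adapt2step
Title: Two-Step IMRT Segmentation and Monitor-Unit-Preserving Plan Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric generation of two-step intensity-modulated radiotherapy
    (IMRT) segments (target-conformal, organ-at-risk-sparing, and narrow
    edge-compensating apertures), adaptation of those segments to a changed
    patient geometry while preserving the planned monitor units, and
    quantitative plan evaluation. Includes generators for horseshoe-phantom and
    synthetic prostate geometries, an idealized exposure-fraction dose engine
    with dose-volume histogram metrics, a composite-objective segment
    fine-tuner with leaf-shift recording, the S_D plan quality score, and an
    exact one-tailed Wilcoxon signed-rank test for paired plan cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    mgcv,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
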