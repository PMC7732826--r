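Package: tapslip
Title: Error Analysis of Continuous Motor Sequence Tapping with Mixed
    Block/Event-Related fMRI Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segments keypress streams from self-paced motor sequence tapping
    into correct trials and errors, applies isolated-error eligibility rules,
    builds position-matched error-free control periods, and quantifies
    block-normalized slowing around errors (onset, within-error, offset,
    post-error).  Provides a mixed block/event-related general linear model
    for BOLD time series with canonical double-gamma HRF convolution, DCT
    high-pass nuisance regressors, AR(1)-plus-white-noise prewhitening,
    trial-wise matched contrasts, sphere-ROI extraction, and second-level
    statistics (one-sample t, repeated-measures ANOVA with Greenhouse-Geisser
    correction, Bonferroni over ROI families).  Includes synthetic keypress
    and BOLD generators carrying full ground truth for recovery testing, and
    a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
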