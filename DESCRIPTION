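Package: glucast
Title: Multimodal Short-Term Forecasting of Continuous Glucose Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for short-term forecasting of interstitial glucose from
    continuous glucose monitoring (CGM) traces in type 2 diabetes. Provides a
    synthetic cohort simulator (two sensor types, baseline-covariate-driven
    glucose dynamics, sensor-dropout missingness), CGM preprocessing (grid
    resampling, linear imputation, min-max scaling, missingness-based
    exclusion, augmented Dickey-Fuller stationarity checks), sliding-window
    construction with leave-one-day-out cross-validation, a from-scratch
    bidirectional LSTM with self-attention and a 1D convolutional feature
    stage optionally fused with a dense encoder of baseline health-record
    variables, and evaluation utilities: mean absolute percentage and point
    errors, hypo-/hyperglycaemic stratification, paired significance tests,
    the Parkes (consensus) error grid for type 2 diabetes and ambulatory
    glucose profile (AGP) summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
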