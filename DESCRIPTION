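Package: vdjkinetics
Title: IMU-Based Estimation of Ground Reaction Forces and Knee Moments
    During Vertical Drop Jump Landings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end pipeline for estimating three-dimensional ground
    reaction forces and knee joint moments during the first landing phase of
    a vertical drop jump from three body-worn inertial measurement units
    (sacrum, right thigh, right shank). Provides uniform-rate signal
    containers with Butterworth filtering and band-limited resampling,
    cross-correlation synchronization of optical and inertial streams via a
    quasi-periodic start-of-session trigger, force-plate contact-phase
    segmentation against a 10 N vertical threshold, assembly of the
    25-column matched training table, a NARX (nonlinear autoregressive with
    exogenous input) network trained with resilient backpropagation on a
    regularized mean-squared-error objective, subject-wise cross-validated
    RMSE evaluation with error histograms, and a synthetic drop-jump cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    ggplot2,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
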