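Package: wayfam
Title: Classifying Spatial Familiarity from Mobile Eye-Tracking and Head-Mounted IMU Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for in-situ spatial-familiarity classification of
    pedestrian wayfinders from wearable sensor streams. Provides a synthetic
    session generator for gaze, head-mounted inertial measurement unit (IMU)
    and GNSS streams with configurable condition-dependent effect sizes;
    preprocessing (zero-phase low-pass filtering, singular spectrum
    transformation change-point scoring, artifact removal, GNSS repair and
    route projection, IMU downsampling, yaw-based time-offset estimation);
    matching-to-action segmentation into fixed three-second windows;
    dispersion-threshold (I-DT) fixation detection and a 28-statistic gaze
    feature bank; a 99-feature IMU descriptor bank (basic statistics, cepstral
    coefficients, time-domain, fundamental period, movement and spectral
    measures); and gradient-boosted tree classification with participant-aware
    validation schemes, log-loss diagnostics and SHAP feature-importance
    ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
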