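Package: gaitfall
Title: Fall-Risk Classification from Shoe-Mounted IMU Gait Analysis
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for fall-risk screening of older adults from
    wearable gait data. Simulates shoe-mounted inertial measurement unit (IMU)
    walking signals and cohort feature tables with known ground truth; filters
    signals with a zero-phase Butterworth low-pass and detects heel-strike and
    toe-off events from anteroposterior and vertical acceleration maxima;
    computes the nine standard spatiotemporal gait variables per walking speed
    (walking speed, stride length, cadence, stance phase, stride time, three
    stride-to-stride coefficients of variation, and gait asymmetry); labels
    participants high or low fall risk from a configurable monotone
    questionnaire rule; trains per-speed gradient-boosted tree classifiers
    under a regularized second-order objective; and reports the full
    evaluation panel (ROC/AUC, sensitivity, specificity, predictive values,
    likelihood ratios, confidence intervals, feature importance, and group
    descriptives).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
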