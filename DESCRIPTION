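Package: gaitseg
Title: Event-Based Gait Segmentation and Activity Classification from
    Shank-Mounted Inertial Sensors
Version: 0.1.0
Authors@R:
    person("gaitseg", "developers", email = "gaitseg@example.org",
           role = c("aut", "cre"))
Description: Streaming rule-based detection of gait events (mid-swing, foot
    strike, foot-off) from the sagittal-plane angular velocity of a
    shank-mounted inertial measurement unit, segmentation of the signal into
    gait cycles delimited by consecutive foot-off events, configurable
    pre-processing (standing-still inclination correction and a causal
    second-order low-pass filter), extraction of a 152-dimensional per-cycle
    feature vector, SVM-weight feature ranking and pairwise support vector
    machine classification of locomotion activities (walking, stair ascent,
    stair descent, running) under leave-one-subject-out and cross-dataset
    protocols. Includes a synthetic shank-IMU signal generator with exact
    ground-truth event annotations and a harness comparing six pre-processing
    configurations end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
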