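Package: gaitscore
Title: Automatic Severity Scoring of Parkinsonian Gait from Shank-Mounted
    Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic assessment of the gait task of the Unified
    Parkinson's Disease Rating Scale (UPDRS) from two shank-mounted inertial
    measurement units. Implements gait event detection from the mediolateral
    shank angular velocity, zero-velocity-update integration of the ankle
    trajectory, extraction of twelve spatio-temporal and kinematic gait
    features, and a bounded parallel-hyperplane nonlinear model that maps the
    features to a continuous severity score on the 0-4 UPDRS scale. Includes
    constrained model fitting, leave-one-subject-out cross-validation,
    ANOVA-based and greedy wrapper feature selection, support vector machine,
    naive Bayes and linear regression baselines, and a two-tier synthetic
    data generator for feature tables and raw 100 Hz IMU trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
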