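Package: aftmon
Title: Continuous Worker-Fatigue Monitoring from Wearable EMG and IMU Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for continuous occupational fatigue
    monitoring from forearm wearable sensors. Simulates labeled multi-rate
    sessions (8-channel surface EMG at 200 Hz, 9-axis IMU at 50 Hz, oxygen
    uptake and heart rate at 1 Hz), synchronizes the streams into per-second
    windows, extracts 289 per-window statistical features, trains bidirectional
    LSTM sequence models for activity recognition and oxygen-uptake regression
    under leave-one-subject-out cross-validation, computes the aerobic fatigue
    threshold (AFT) against activity-specific maximum aerobic capacity, and
    classifies five fatigue levels with a panel of classical machine-learning
    classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    data.table,
    jsonlite,
    yaml,
    MASS,
    nnet,
    class,
    rpart,
    randomForest,
    e1071,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
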