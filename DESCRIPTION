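Package: escalert
Title: Multimodal Wearable-Sensor Prediction of Imminent Behavioral Escalation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting imminent precursors of
    problem behavior in children from multimodal wearable recordings: a
    seven-IMU upper-body motion garment (accelerometer/magnetometer tilt
    orientation and forward-kinematic pose reconstruction), wrist physiology
    (blood volume pulse heart rate, tonic/phasic electrodermal activity,
    three-axis acceleration) and face/head tracking, aligned against
    millisecond-precision behavioral event logs produced under an
    IISCA-style functional-analysis session protocol. Includes the session
    state machine used to validate event logs, windowed pre-event labeling,
    seven classifier families with individualized and leave-one-subject-out
    evaluation, impurity-based feature and modality importances, and a
    seeded synthetic multimodal cohort simulator so every stage is testable
    without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    tools,
    ggplot2,
    signal,
    pracma,
    yaml,
    jsonlite,
    stats,
    utils,
    randomForest,
    e1071,
    rpart,
    nnet,
    class,
    MASS,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
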