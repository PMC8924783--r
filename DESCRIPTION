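Package: wristfork
Title: Eating Detection from Wrist-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete analysis pipeline for detecting eating events from
    free-living wrist accelerometer and gyroscope streams with diary labels:
    a synthetic-data generator emulating free-living recording days,
    delimited-text record I/O, participant- and day-level quality cleaning,
    sliding-window segmentation with three-way labelling and oversampling,
    per-window normalization and rotation/scaling augmentation, a ten-block
    one-dimensional convolutional network trained with Adam and ensembled
    over resampled splits, personal fine-tuning, an imbalanced-class metric
    suite with a resampling significance test, and meal-level aggregation
    with alarm ('call') logic and hourly false-positive rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
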