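Package: gaitwear
Title: Gait-Phase Segmentation from Wearable Textile-Pressure and IMU Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for rule-based gait-phase annotation and
    classification from wearable sensors. Simulates keypoint tracks and
    multichannel textile-pressure/IMU recordings of back-and-forth walking
    trials with synchronization jumps; labels gait phases (single support on
    either side, double support, not-considered turnaround zones) from heel
    and toe landmark velocities; synchronizes the label clock to the
    acquisition clock via jump detection; applies a signal conditioning chain
    (turnaround and invalid-sample removal, robust outlier replacement,
    zero-phase Butterworth low-pass, per-channel z-normalization, ARFF
    export); extracts windowed time/frequency features with
    false-discovery-rate relevance selection; and benchmarks a random forest
    and a time series forest with per-class precision and confusion-matrix
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    e1071,
    foreign,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
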