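Package: weakbeat
Title: Weakly Supervised Beat-by-Beat ECG Arrhythmia Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains beat-by-beat electrocardiogram (ECG) arrhythmia detectors
    (AAMI classes N / SVEB / VEB) from record-level label sets only. A 1D
    residual convolutional network makes per-sample local predictions which
    are fused with two knowledge-based RR-interval feature maps (relative RR
    interval and RR sample entropy), aggregated at R-peak positions by masked
    global max pooling, and optimized end-to-end with a weighted binary
    cross-entropy on the record labels. Includes classical aggregation
    baselines (global average / max pooling, log-sum-exp), an optional
    supervised pre-training stage on finely annotated beats, AAMI-style
    beat-level evaluation (sensitivity, specificity, positive predictivity,
    accuracy, F1, precision-recall curves and average precision), a seeded
    synthetic single-lead ECG generator with known beat-level truth, and
    readers for WFDB-style records and a simple columnar text format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
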