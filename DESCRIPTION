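Package: ctlmon
Title: Cognitive Task-Load Monitoring and Adaptive Task Allocation from
    EEG and ECG Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for physiology-based monitoring of operator cognitive
    task-load (CTL) in human-machine process control, and for simulating
    closed-loop adaptive automation driven by the monitored state.
    Implements recursive-least-squares ocular artifact removal, epoch-wise
    EEG band-power and heart-rate feature extraction, adaptive exponential
    smoothing, per-channel locality preserving projection, dynamic NARX
    least-squares support-vector-machine performance predictors with
    five-class discretization, multiclass evaluation (confusion matrices,
    per-class accuracy, cumulative false positive/negative rates), and a
    closed-loop task-reallocation simulator with proportional-threshold
    and rule-based controllers. A synthetic operator-data generator
    reproduces the statistical structure the method assumes so the whole
    pipeline can be exercised without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
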