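Package: nestscale
Title: Dynamic Weighing of Unrestrained Animals from Smart Nest-Box Scales
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Processing pipeline for raw streams from an automatic scale
    placed in the entry corridor of a nest box: robust tare auto-calibration
    by iteratively reweighted least squares, annual gain calibration,
    range filtering and threshold-based segmentation of weighing patterns,
    run-length and frequency feature extraction, and a dual-path body-weight
    estimator (mean of stable readings when the scale reports any, otherwise
    a small multilayer perceptron applied to nine pattern summaries).
    Includes the offline back-propagation training protocol with a
    hidden-size sweep, telemetry payload accounting for local aggregation,
    and a synthetic visit simulator with known ground truth so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
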