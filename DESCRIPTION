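Package: steplr
Title: Step Counting from Accelerometry via Left/Right Step Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Device-agnostic step counting from tri-axial accelerometer
    recordings. Implements the full pipeline: reading and resampling of
    raw acceleration time series, the Euclidean-Norm-Minus-One (ENMO)
    orientation-robust feature, stride-1 sliding-window datasets labeled
    by the step side (left/right) of the window's last sample, three
    small neural-network classifiers (a shallow CNN, a WaveNet-style
    dilated causal convolutional network with gated residual blocks, and
    a two-layer LSTM) trained with Adam and accuracy-monitored early
    stopping, subject-wise shuffled cross-validation, per-subject domain
    adaptation on a short labeled calibration walk, and transition-based
    step-count metrics. Includes a synthetic gait simulator so the whole
    pipeline can be exercised end to end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
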