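Package: skelrepair
Title: Repair and Ergonomic Scoring of 2D Pose Skeleton Sequences
Version: 0.1.0
Authors@R:
    person("skelrepair", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Post-processing of 2D human pose sequences (OpenPose BODY_25
    dialect) for ergonomic risk assessment of caregiving tasks. Detects
    missing and misidentified skeleton frames with temporal kinematic-chain
    matrices, repairs them by anchored linear interpolation and
    dominant-action-feature correction with Kalman smoothing, then computes
    the eight REBA joint angles, REBA scores and risk levels. Ships a
    synthetic articulated-motion generator with corruption injection so the
    whole pipeline is testable without video data, a miniature
    spatial-temporal graph convolutional action classifier, and evaluation
    metrics (MAE, missing/misidentification rates, REBA accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
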