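Package: trackloop
Title: Closed-Loop 1D Track Experiment Control and Place-Cell Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A software-only control plane for head-fixed one-dimensional
    navigation experiments: a routed JSON datagram message bus with
    acknowledged delivery, rotary-encoder position integration with lap
    wrap and lap-reset drift correction, a composable context engine
    (reward zones, decorators, operant and non-operant reward rules), a
    streaming JSON-lines behavior log, and a fully virtual rig (simulated
    mouse, position controller, behavior controller, display stub) so that
    complete closed-loop sessions run with known ground truth.  On the
    analysis side it implements event binarization, occupancy-normalized
    tuning curves, circular-shuffle place-field detection, place-cell
    sensitivity, specificity and spatial information, remapping statistics,
    and naive-Bayes population position decoding with cross-validated
    error and chance levels, together with a seeded synthetic place-cell
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
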