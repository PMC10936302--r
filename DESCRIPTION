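Package: gaitintent
Title: Data-Efficient Walking Speed Intent Identification from Cyclic Gait Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Real-time identification of a walker's intent to speed up, slow
    down, or keep a constant pace from multichannel kinematic time series.
    Walking at constant speed is modeled as a cyclostationary process: each
    timestep of each gait phase (left/right double and single support) carries
    its own multivariate Gaussian distribution, trained recursively from a few
    minutes of constant-speed data. Incoming frames are scored by squared
    Mahalanobis distance against the matching cell, low-pass filtered, and
    compared to a chi-squared calibrated threshold; phase-timing mismatches
    provide additional triggers, and the duration of the most recently
    completed gait cycle types a detected change as speed-up or slow-down.
    Includes a synthetic treadmill-protocol gait generator, phase segmentation
    from foot contacts or a virtual-leg vector, and evaluation tools
    (per-timestep confusion matrices, per-class metrics, detection delays,
    threshold trade-off sweeps, model-convergence curves, and
    distance-versus-speed regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
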