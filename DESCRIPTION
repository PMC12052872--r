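Package: emgchrono
Title: EMG-Based Chronometric Decomposition of Two-Choice Reaction Times
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to decompose two-choice reaction times into premotor and
    motor components from surface electromyography (EMG) recorded over the
    response effectors. Implements zero-phase high-pass and notch filtering,
    stimulus- and onset-locked epoching, integrated-profile EMG onset
    detection, supra-threshold activity-window detection with merge and
    minimum-duration rules, covert partial-error and partial-correct
    detection on the non-responding channel, trial classification,
    conditional accuracy and incorrect-activation functions over response
    latency quantiles, within-participant (Morey-adjusted) confidence
    intervals, a BIC-based Bayes-factor approximation, and EMG-burst shape
    metrics (mean amplitude to the 30%-of-peak return and rising-flank
    slope). A synthetic-data generator produces two-channel recordings and
    event tables with known ground truth for a speed-accuracy tradeoff by
    lexicality design, so the whole measurement chain can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
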