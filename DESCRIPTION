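Package: wristfall
Title: Fall Detection from Wrist-Worn Accelerometer Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting falls in tri-axial accelerometer streams
    recorded by wrist-worn devices sampling at smartwatch rates (31.25 Hz).
    Provides labelled-trace CSV input/output and random-sample stream
    resampling, resultant-acceleration sliding-window features (Ares, Smin,
    Smax, Delta-S) in batch and streaming form, Gaussian naive Bayes and
    support-vector per-sample classifiers combined with a consecutive-count
    event decision rule, a small gated-recurrent-unit (GRU) sequence detector
    with moving-average probability smoothing, an event-based evaluation
    protocol (per-instance precision, recall and accuracy), and a synthetic
    wrist-signal generator covering three fall morphologies and scripted
    activities of daily living so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
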