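Package: entrofuse
Title: Entropy Feature Fusion and Team-Collaboration Classification for
    Physiological Emotion Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for recognising emotional states from multi-channel
    peripheral physiological recordings (ECG, EMG, respiration, skin
    conductance and similar). Four nonlinear regularity features --
    approximate entropy, sample entropy, fuzzy entropy and wavelet packet
    energy entropy -- are extracted per channel window, fused by
    concatenation across channels, and classified with a team-collaboration
    strategy: a one-vs-one RBF support vector machine acts as the main
    decider, and a gain-ratio decision tree plus an extreme learning machine
    arbitrate samples whose vote margins flag them as likely misclassified.
    Includes a hold-out evaluation protocol and a synthetic-data generator
    with class-dependent signal complexity, so the whole pipeline runs
    without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    quadprog,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
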