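Package: cvep
Title: Simulation and Decoding of Code-Modulated Visual Evoked Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-speed brain-computer interfaces driven by
    code-modulated visual evoked potentials (c-VEP). Implements the
    EEG2Code backward model, which predicts each bit of a binary visual
    stimulation pattern from the following 250 ms of multichannel EEG:
    a closed-form linear ridge regression baseline and a five-layer
    convolutional network with spatial and temporal filter layers.
    Includes generation of random stimulation codes, a forward
    simulator producing EEG-like recordings by linear superposition of
    single-flash responses with pink noise and an optional saturating
    nonlinearity, synchronous correlation-based target classification,
    asynchronous self-paced selection by correlation p-value
    thresholding, discrimination among very large candidate code sets,
    and the standard BCI performance measures (information transfer
    rate, utility bitrate, correct letters per minute).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
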