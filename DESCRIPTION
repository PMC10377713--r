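Package: gapdpl
Title: Genetically Optimized Projection Dictionary Pair Learning for
    Multi-Subject EEG Features
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Trains per-class synthesis/analysis dictionary pairs
    (projection dictionary pair learning, PDPL) with closed-form
    alternating updates and an ADMM step for the norm-constrained
    synthesis dictionary, and classifies samples by minimum
    reconstruction residual. The four PDPL hyperparameters (dictionary
    size m, code-coupling tau, discrimination weight lambda, ridge
    gamma) are tuned by a Gray-coded genetic algorithm with stochastic
    universal sampling and elitist reinsertion, using
    leave-one-subject-out mean accuracy as fitness. Includes a
    log-spectral-power EEG feature extractor (order-8 zero-phase
    Butterworth band-pass, 1 s RMS windows) and synthetic multi-subject
    generators for offline testing.
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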