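Package: soundstates
Title: Cross-State Analysis of Auditory Neural Population Codes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing sound representations in the same neurons
    across brain states (e.g. wakefulness and anesthesia) at the desk scale.
    Provides a generator for a 307-sound stimulus battery and block-structured
    session schedules, an inhomogeneous-Poisson two-state population simulator
    with state-dependent response remodeling (silencing, gain changes, sign
    flips), robust signal statistics (MAD noise estimate, spike SNR), per-unit
    response metrics (PSTH, spontaneous rate, reliability, best frequency,
    tuning half-width in octaves, ramp intensity threshold, response-change
    classification), cross-state unit matching by template correlation against
    an empirical chance null, pseudo-population nearest-neighbor sound decoding
    within and across states with a neuron-level bootstrap, and a
    principal-component state-subspace analysis with a cross-validated linear
    maximum-margin state classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
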