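Package: thermoEEG
Title: Spectral, Spatio-Temporal and Decoding Analysis of EEG Responses
    to Thermal Stimuli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing and decoding scalp EEG responses to
    graded thermal stimulation of the hand. Implements a seeded synthetic-data
    generator emulating a five-condition thermal stimulation paradigm (64
    channels at 512 Hz, alpha-band event-related desynchronization scaled by
    stimulus discomfort, condition-specific evoked transients, injected
    artifacts, behavioral ratings, and robot-skin contact temperature
    profiles), zero-phase Butterworth/notch preprocessing with threshold and
    EMG-band artifact rejection, Welch band power and ERD indices, global
    field power, evoked peak detection, a common spatial patterns ->
    PCA -> linear discriminant decoding chain with sliding-window crop
    augmentation and balanced-accuracy evaluation, the accompanying
    nonparametric statistical tests, and a time-domain-feature classifier for
    robot-skin temperature levels with a withdrawal policy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    MASS,
    class,
    e1071,
    nortest,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
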