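Package: kcdetect
Title: K-Complex Detection in Sleep EEG via Recursive Reassigned
    Cohen-Class Time-Frequency Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for detecting K-complexes in single-channel sleep
    electroencephalograms. Implements discrete Cohen-class energy
    distributions (spectrogram, pseudo and smoothed-pseudo Wigner-Ville,
    Born-Jordan, Choi-Williams, Zhao-Atlas-Marks), their reassigned
    (reallocated) variants with time- and lag-modified kernels, and a
    streaming recursive evaluation of the smoothed-pseudo Wigner-Ville
    distribution whose per-step cost is independent of the time-smoothing
    support. A synthetic stage-2 sleep-EEG generator (K-complexes, sleep
    spindles, delta background, slow wave, mains hum), an IIR notch
    preprocessing stage, a fixed-length feature extractor, and a
    from-scratch multilayer perceptron with arctan/tanh/sigmoid
    activations trained by single-example stochastic gradient descent
    complete an end-to-end detection pipeline with event-level scoring.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
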