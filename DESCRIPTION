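Package: cisim
Title: Cochlear-Implant Simulation with a Channel-Picking Noise Vocoder and
    Psychophysical Tuning-Curve Tools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Acoustic simulation of cochlear-implant hearing with a
    20-channel n-of-m noise-band vocoder whose synthesis filters have
    parametric slopes emulating spread of excitation, together with the
    psychoacoustic machinery needed to characterise the simulation:
    forward-masking psychophysical tuning curves measured with a
    three-interval forced-choice two-up one-down adaptive staircase against
    a simulated listener, two-sided quadratic tuning-curve fits with Q10dB
    sharpness, rationalized arcsine (RAU) transformation of word scores,
    stimulus generators (tones, masker-probe sequences, babble-like noise,
    synthetic word tokens, SNR mixing), and WAV input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
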