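Package: polfret
Title: Single-Molecule FRET Analysis of DNA Polymerase Fingers Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule FRET (smFRET)
    time series reporting on the fingers-open/fingers-closed conformational
    cycle of a DNA polymerase (Klenow fragment) during DNA synthesis.
    Provides a kinetic Monte Carlo simulator of the nucleotide-addition
    cycle rendered as camera-frame donor/acceptor intensity traces (and
    optional TIFF movies), intensity-threshold binding-event detection,
    variational-Bayes hidden Markov segmentation of FRET states with
    maximum-evidence model selection, censored exponential and
    hypoexponential dwell-time kinetics, post-synchronised ensemble
    analysis, and colour-coded population heat maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
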