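Package: fretscape
Title: Conformational State and Energy Landscapes from Single-Molecule FRET Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-channel single-molecule FRET (smFRET)
    intensity trajectories of membrane receptors: photobleaching-step trace
    selection, proximity-ratio efficiency calculation, wavelet denoising,
    conformational-state identification by t-test change-point segmentation
    with minimum-description-length model selection (STaSI-style) and by
    Gaussian-emission hidden Markov modelling, Forster efficiency-to-distance
    conversion, and state-occupancy based free-energy and transition-barrier
    landscapes.  Includes a synthetic photon-trace simulator with Markovian
    conformational dynamics, Poisson shot noise, stochastic photobleaching and
    mixed labelling stoichiometry, so every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
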