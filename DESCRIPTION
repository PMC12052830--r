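Package: vortexflux
Title: Localization Precision Analysis for Vortex-Beam MINFLUX Nanoscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analyzing and simulating MINFLUX and RASTMIN
    single-emitter localization with Laguerre-Gaussian vortex excitation
    beams of arbitrary order. Provides the beam intensity model and its
    radial sensitivity, the two standard targeted coordinate patterns,
    multinomial photon-detection models with explicit signal-to-background
    conventions, analytic Fisher-information and Cramer-Rao bounds
    (numeric and closed form), precision maps, effective field-of-view and
    optimal-pattern-size searches, the Van Trees bound under a Gaussian
    positional prior, and a seeded Monte-Carlo maximum-likelihood
    localization simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
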