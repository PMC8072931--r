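Package: ptbind
Title: Binding Thermodynamics of Platinum(II) Complexes with Model Proteins
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Characterizes the interaction of platinum(II)
    terpyridine-class anticancer complexes with small model proteins
    (hen egg-white lysozyme, ribonuclease A). Provides iterative
    linearized estimation of 1:1 binding constants from differential
    UV-Vis titrations, Scatchard analysis of equivalent sites, an exact
    mass-action equilibrium solver with a direct nonlinear-least-squares
    cross-check, two-state van't Hoff analysis of DSC excess heat
    capacity curves (baseline subtraction, enthalpy integration,
    denaturation temperature and entropy), molecular-formula mass
    bookkeeping for metal-fragment adduct assignment against deconvolved
    ESI-MS neutral masses, a minimal charge-envelope deconvolver, and
    seeded simulators for titration spectra, thermograms and ESI
    envelopes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
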