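Package: plantarQLV
Title: Quasi-Linear Viscoelastic Characterization of Plantar Aponeurosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for the time-dependent mechanical response of
    human plantar aponeurosis tissue. Implements a transversely isotropic
    fiber-reinforced hyperelastic material under incompressible uniaxial
    tension, quasi-linear viscoelasticity with a Prony-series reduced
    relaxation function, a recursive exponential time integrator for
    arbitrary strain histories, stress-relaxation curve fitting by a
    stochastic-deterministic (simulated annealing plus Nelder-Mead)
    procedure with model selection over the number of viscous branches,
    strain-level invariance testing by one-way ANOVA, and a seeded
    generator of virtual stress-relaxation experiments emulating the
    tissue-testing protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
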