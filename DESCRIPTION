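Package: burstscan
Title: Bifurcation-Based Screening of Bursting Neuron Models for
    Multistability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for extending brute-force parameter databases of
    conductance-based neuron models with stationary-state information.
    Implements declarative single-compartment Hodgkin-Huxley-type models
    and two-cell half-center oscillators, stiff integration (implicit
    Radau IIa of order 5 via deSolve), spike/burst trace classification,
    pseudo-arclength continuation of equilibria with fold and
    Andronov-Hopf detection, iterative scanning of the leak-conductance
    range supporting robust bursting, systematic detection and
    classification of coexisting bursting and rest states, a
    reset-perturbation protocol for half-center oscillators, and a
    relational results store. Ships analytically tractable surrogate
    models (fold and Hopf normal forms, a relaxation oscillator, and a
    minimal fast-slow endogenous burster) so that every pipeline stage
    is testable against independent oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
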