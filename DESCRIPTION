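Package: cmekit
Title: Stochastic Chemical Kinetics from a Single Reaction-Network Definition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives, compiles and integrates microscopic, mesoscopic and
    macroscopic descriptions of stochastic chemical reaction networks from a
    single declarative model definition. Implements exact stochastic simulation
    (direct, next-reaction, and modified next-reaction methods with
    time-dependent propensities and fixed delays), the finite state projection
    of the chemical master equation with a certified mass-defect error bound,
    moment equations of arbitrary order with selectable closure schemes,
    the system size expansion (reaction rate equations, linear noise
    approximation, effective mesoscopic rate equation, and inverse-omega-square
    corrections), the method of conditional moments for hybrid low/high
    copy-number systems, and forward (first- and second-order) and adjoint
    sensitivity analysis for least-squares objectives. Networks can be defined
    natively, read from YAML configuration files, or imported from SBML.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
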