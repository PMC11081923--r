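Package: DomainNMR
Title: Solution NMR Analysis of Multi-Domain Proteins: Shifts, Dynamics,
    Exchange and Residual Dipolar Couplings
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the solution-NMR characterisation of multi-domain
    proteins such as tandem BRCT domains. Implements chemical-shift
    assignment completeness statistics, titration chemical-shift
    perturbation mapping, CA/CB secondary-shift secondary-structure
    classification, heteronuclear NOE backbone-dynamics analysis with
    Monte-Carlo uncertainties, hydrogen-deuterium exchange protection
    classing, and residual-dipolar-coupling alignment-tensor fitting,
    including a nested two-domain model with shared magnitude and
    rhombicity compared by F-test to detect interdomain reorientation.
    A synthetic-data module generates ground-truth-labelled inputs for
    every stage, so the full pipeline is testable without spectrometer
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
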