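Package: thermokin
Title: Thermodynamics-Based Flux Analysis and Kinetic Model Ensembles for
    Compartmentalized Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and exercising thermodynamically curated
    constraint-based models of bacterial metabolism. Implements flux balance
    analysis and thermodynamics-based flux analysis (TFA) as mixed-integer
    linear programs, including a compartment-resolved integration of whole-cell
    metabolomics built on Jensen's inequality for volume-weighted
    concentrations; thermodynamic variability analysis; metabolic-task-driven
    MILP gap-filling; Monte-Carlo construction of ensembles of log-linear
    kinetic models with elasticity sampling, stability filtering and metabolic
    control analysis; and classifier-based refinement of kinetic-parameter
    ranges. Ships a synthetic two-compartment network generator with a known
    nonlinear kinetic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    deSolve,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: python (>= 3.8) with scipy (>= 1.9) on PATH, used as the
    LP/MILP solving backend (HiGHS).
Config/testthat/edition: 3
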