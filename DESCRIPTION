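Package: ethanolWBM
Title: Coupled Physiologically-Based Pharmacokinetic and Whole-Body
    Metabolic Modelling of Ethanol and Acetaldehyde
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A 17-compartment physiologically-based pharmacokinetic (PBPK)
    model of ethanol and acetaldehyde coupled, by dynamic flux balance
    analysis, to a reduced whole-body stoichiometric network of ethanol
    metabolism and excretion. Organ volumes, blood flows and tissue-plasma
    partition coefficients are derived from an individual's anthropometrics;
    hepatic alcohol and aldehyde dehydrogenase kinetics set time-varying flux
    bounds for a linear program whose solution drives the ODE system between
    re-solves triggered by a relative-deviation tolerance. Scenario engines
    cover drink-strength absorption, liver enzyme expression, ALDH2
    polymorphisms, disulfiram inhibition and multi-dose regimens, with a
    synthetic clinical-study generator, absorption-parameter fitting, and
    AUC/MAE exposure metrics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    boot,
    MASS,
    deSolve,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
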