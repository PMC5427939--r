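Package: rampflux
Title: Robust Analysis of Metabolic Pathways for Genome-Scale Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis of genome-scale metabolic models in
    which the steady-state equalities of flux balance analysis (FBA) are
    replaced by scenario-based chance constraints on uncertain stoichiometric
    coefficients (the RAMP method). Provides model readers for SBML (level 3,
    fbc) and COBRA-style JSON, deterministic FBA, scenario builders for
    digit-level, scaled, proportional and percentile-varied uncertainty in the
    biomass equation, assembly and solution of the robust problem in both its
    linearized and second-order-cone forms, L1-minimal calibration of the
    steady-state deviation bounds, gene-essentiality knockout screens with
    confusion-matrix scoring, maximal-uncertainty search for single biomass
    coefficients, and quadratic fitting of model fluxes to experimental
    measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    quadprog,
    jsonlite,
    methods,
    rlang,
    xml2,
    tibble,
    dplyr,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
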