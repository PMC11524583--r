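Package: bbbivivc
Title: In Vitro-In Vivo Correlation of Blood-Brain Barrier Permeability
    from Transwell Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for predicting in vivo blood-brain barrier
    permeability from in vitro Transwell transport assays. Computes apparent
    permeability coefficients (Papp) from single-timepoint receiver
    concentrations with mass-balance and sink-condition QC, normalizes and
    summarizes TEER barrier-integrity time courses, scales Papp to predicted
    permeability-surface-area products (PS) via the brain vascular surface
    area and the brain unbound fraction, and evaluates predictions against
    observed in situ brain-perfusion PS values with a 0.5- to 2-fold success
    criterion and geometric fold-error summaries. Includes comparative-Ct
    qPCR fold-change and simple linear regression helpers for
    expression-permeability correlations, a mechanistic two-compartment
    simulator of the Transwell assay, and a synthetic drug-cohort generator
    so every stage is testable end to end. Ships an 18-drug reference dataset
    of measured Papp, unbound fractions and literature PS values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
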