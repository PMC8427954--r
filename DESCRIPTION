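Package: umsspd
Title: Ordinal Sigmoid-Emax Pharmacodynamics of Propofol Sedation in Children
Version: 1.0.0
Authors@R: person("Pharmacometrics", "Toolbox", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Population pharmacodynamic analysis linking effect-site propofol
    concentration (Ce) to the ordinal University of Michigan Sedation Scale
    (UMSS, 0-4) in children. Implements the ordinal sigmoid-Emax probability
    model with per-threshold Ce50 values and a shared Hill coefficient,
    naive-pooled maximum-likelihood estimation with Wald standard errors and
    confidence intervals, subject-resampling bootstrap validation, prediction
    probability (Pk, Somers' d based) evaluation with jackknife confidence
    intervals, most-probable-score prediction tables, and Bland-Altman percent
    agreement between concentration predictions. A three-compartment plus
    effect-site pharmacokinetic simulator with infusion-log replay, an
    idealized effect-site target-controlled infusion controller, and a
    synthetic-study generator allow the full pipeline to run with no external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
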