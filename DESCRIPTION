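Package: pkadherence
Title: Pharmacokinetics-Based Monitoring of Adherence to Atorvastatin Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating patient adherence to atorvastatin therapy
    from sparsely sampled therapeutic drug monitoring data. Implements a
    closed-form one-compartment oral absorption model with repeat dosing,
    a nonparametric maximum-likelihood population fit (adaptive grid with
    EM mixture-weight updates), Monte Carlo simulation of adherent,
    partially adherent and nonadherent virtual cohorts, ROC-based cutoff
    selection on dose-normalized concentrations, and a probability-of-
    attainment classifier that labels individual patients as adherent,
    partially adherent or nonadherent. A seeded synthetic-cohort generator
    reproduces the sparse sampling design of the motivating clinical study
    so that every pipeline stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
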