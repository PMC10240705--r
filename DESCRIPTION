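Package: copdbia
Title: Budget-Impact Analysis of Digital Inhaler Monitoring in COPD
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A prevalence-based, deterministic budget-impact model of a
    digital inhaler-monitoring platform for chronic obstructive pulmonary
    disease (COPD), from commercial and Medicare payer perspectives.
    Computes eligible-population counts from age-stratified prevalence,
    per-patient annual cost breakdowns by GOLD 2017 ABCD group
    (hospitalizations, emergency department visits, outpatient visits,
    rescue and controller inhalers, remote therapeutic monitoring fees,
    platform subscription), per-member-per-month (PMPM) budget impact
    over a three-year uptake horizon, adherence-linked scenario analyses,
    one-way sensitivity sweeps, and break-even / budget-neutrality
    solvers.  A patient-level Monte-Carlo cohort simulator with the same
    expectation as the deterministic engine serves as an internal
    validation oracle.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
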