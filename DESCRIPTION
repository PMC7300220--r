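Package: sirodose
Title: Population Pharmacokinetics and Initial Dose Simulation for
    Sirolimus in Children
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nonlinear mixed-effects population pharmacokinetic modelling
    of sparse sirolimus therapeutic-drug-monitoring data from children
    with tuberous sclerosis complex, and Monte-Carlo simulation of
    starting doses.  Implements a one-compartment first-order-absorption
    model with allometric weight scaling, first-order conditional
    estimation with interaction (FOCE-I), stepwise covariate selection by
    likelihood-ratio thresholds, subject-level bootstrap and
    prediction-corrected visual predictive checks, steady-state trough
    simulation with probability of target attainment over a weight by
    dose by regimen grid, and Pearson chi-squared Hardy-Weinberg
    equilibrium tests for the accompanying pharmacogenetic tables.  A
    synthetic-data module generates therapeutic-drug-monitoring cohorts
    with the same hierarchical variability structure so the whole
    pipeline is testable without patient data.
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
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
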