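Package: ecudose
Title: Population Pharmacokinetic-Pharmacodynamic Simulation of Eculizumab Dosing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for eculizumab dosing in atypical haemolytic
    uraemic syndrome (aHUS). Implements a one-compartment population
    pharmacokinetic model with parallel first-order and Michaelis-Menten
    (target-mediated) elimination, a sequential inhibitory sigmoid Emax model
    linking free drug concentration to classical complement pathway (CP)
    activity, lognormal interindividual and interoccasion variability, and
    allometric body-weight scaling. On top of the model it provides a virtual
    population generator, weight-banded dosing regimens (label, weight-based
    loading, fixed 4-week interval), a trough-guided therapeutic drug
    monitoring policy, a Monte Carlo virtual-trial engine with target
    attainment and vial-based drug-cost endpoints, maximum a posteriori (MAP)
    individual parameter estimation for model-informed precision dosing, and
    Passing-Bablok and Bland-Altman method-comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stats,
    utils,
    ggplot2,
    jsonlite,
    yaml,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
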