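Package: scaloop
Title: Closed-Loop Simulation Testing of Age-Structured Stock Assessment Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained framework for simulation testing of age-structured
    fisheries stock-assessment methods. An operating model projects the true
    population dynamics of a virtual fish stock (Beverton-Holt recruitment with
    lognormal deviations, Baranov catch, logistic selectivity), sampling
    functions generate noisy survey indices and multinomial age- and
    length-composition data from that truth, and a maximum-likelihood
    statistical catch-at-age estimation model (written as a TMB template with
    automatic differentiation) is fitted to the sampled data. A scenario engine
    driven by semicolon-delimited plain-text case files crosses data,
    estimation, fishing-mortality, natural-mortality and retrospective cases
    over stochastic iterations with reproducible seeds, and results functions
    harvest everything into long-format scalar and time-series tables with
    paired operating-model and estimation-model columns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    TMB,
    dplyr,
    generics,
    parallel,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    TMB,
    RcppEigen
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
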