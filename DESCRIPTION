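Package: milksem
Title: Bayesian Structural Equation Models for Multi-Trait Sire Models of
    Milk Coagulation Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits recursive structural equation models (SEM) and the baseline
    multiple trait model (MTM) for four milk phenotypes (somatic cell score,
    casein percentage, rennet coagulation time and curd firmness a30) on a
    sire/herd/permanent-environment mixed model, by Metropolis-Hastings-within-
    Gibbs sampling. Includes a sire-maternal-grandsire pedigree relationship
    matrix builder, a synthetic test-day data generator calibrated to Italian
    Holstein study conditions, MTM-scale transformation of SEM covariance
    draws, and posterior summaries (heritabilities, genetic and phenotypic
    correlations, standard-deviation-unit causal effects, variance losses,
    highest posterior density intervals, effective sample sizes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    coda,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
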