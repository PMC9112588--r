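Package: gsbench
Title: Genomic Prediction Benchmarking for Pig Reproduction Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and benchmarking toolkit for genomic prediction of
    lowly heritable, repeated-record reproduction traits in pig breeding
    populations. Provides a gene-dropping simulator for pedigrees, SNP
    genotypes and repeatability-model phenotypes; pedigree and genomic
    relationship matrices including the single-step H-inverse; average
    information REML for the animal repeatability model and derivation of
    corrected phenotypes; GBLUP and single-step GBLUP; a horseshoe-prior
    Bayesian marker regression fitted by Gibbs sampling; support vector
    regression, kernel ridge regression, random forest and Adaboost.R2
    regressors with grid search over hyperparameters; and an evaluation
    driver for repeated five-fold cross-validation and forward (by birth
    date) validation with accuracy, dispersion bias, error metrics and the
    Hotelling-Williams test for dependent correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
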