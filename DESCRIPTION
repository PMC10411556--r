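Package: mtsvr
Title: Multitask Support Vector Regression for Whole-Genome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction of complex traits with (quasi) multitask
    support vector regression (QMTSVR): multitask scaled radial-basis-function
    block kernels over SNP genotypes, an epsilon-insensitive support vector
    regression dual solver (SMO) on precomputed kernels, SNP (co)variance
    weighted kernels, genetic-algorithm hyperparameter tuning, forward-in-time
    CV1/CV2 validation designs, and the associated predictive-ability metrics.
    Includes Gaussian-kernel Bayesian mixed-model benchmarks (single- and
    bi-trait GBLUP/RKHS via Gibbs sampling) and a multi-generation breeding
    population simulator for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab,
    jsonlite,
    optparse
Config/testthat/edition: 3
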