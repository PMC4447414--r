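Package: toycell
Title: A Stochastic Whole-Cell Surrogate for Benchmarking Parameter Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-creation of a whole-cell model parameter-estimation
    challenge. Provides a fast stochastic surrogate cell whose doubling time
    depends on promoter binding probabilities, RNA half-lives and reaction
    turnover numbers; sensitivity-weighted in silico mutant construction; eight
    simulated data classes with budgeted perturbation-data release; log-ratio
    parameter and least-squares prediction scoring with empirical meta-vector
    p-values; a hybrid differential-evolution/random-forest estimator with
    strict below-median acceptance; and reduced physical-model estimators that
    invert the surrogate's steady-state relations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ranger
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
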