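Package: targetmr
Title: Drug-Target Mendelian Randomization with Mediation and Colocalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-sample and drug-target Mendelian randomization from GWAS
    summary statistics. Provides readers and allele harmonization for
    summary-statistic tables, cis-instrument selection with greedy LD
    clumping and Steiger directionality filtering, instrument-strength
    F statistics, a suite of causal-effect estimators (inverse-variance
    weighted, MR-Egger, weighted median, weighted mode, maximum
    likelihood, multivariable MR), heterogeneity and pleiotropy
    diagnostics with leave-one-out analysis, statistical power,
    Benjamini-Hochberg adjustment, cross-consortium meta-analysis,
    two-step mediation decomposition, Bayesian colocalization via
    Wakefield approximate Bayes factors, and a synthetic summary-data
    generator for closed-loop validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    metafor,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
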