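Package: triomr
Title: Within-Family Mendelian Randomization with Simulated Family Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation toolkit for within-family Mendelian
    randomization in mother-father-child trios. Provides a forward simulator of
    trio cohorts with configurable population stratification, assortative
    mating, dynastic (genetic nurture) effects, pleiotropy, and a causal effect
    of child body mass index on continuous symptom outcomes; polygenic score
    construction from GWAS weight tables (greedy LD clumping, allele
    harmonisation, ancestry principal components); two-stage least squares
    estimators for classic and trio-instrumented within-family Mendelian
    randomization with heteroskedasticity- and cluster-robust standard errors
    and conditional instrument-strength diagnostics; summary-statistic
    sensitivity estimators (inverse-variance weighted, MR-Egger, weighted
    median, mode-based); assortative-mating diagnostics; and simulation-based
    power and minimum-detectable-effect analysis.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils,
    yaml
Suggests:
    lmtest,
    optparse,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
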