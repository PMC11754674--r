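Package: protscreen
Title: Proteome-Wide Mendelian Randomization Mediation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for screening circulating proteins as
    mediators between an exposure (such as adiposity) and a disease outcome
    (such as colorectal cancer) using two-sample Mendelian randomization on
    GWAS summary statistics. Implements summary-statistic harmonization, LD
    clumping and proxy lookup, genome-wide and cis-pQTL instrument selection,
    univariable MR estimators with sensitivity analyses (IVW multiplicative
    random effects, Wald ratio, MR-Egger, weighted median, weighted mode,
    leave-one-out, Steiger directionality), multivariable MR with conditional
    F-statistics and generalized Cochran's Q, single-causal-variant
    approximate-Bayes-factor colocalization with a window/prior sensitivity
    grid, spectral-decomposition effective-number-of-tests correction, a
    four-step decision engine issuing mediation calls, and a summary-level
    GWAS simulator with known causal structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
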