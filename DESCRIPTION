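Package: mrtriad
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomization (MR)
    and two-step mediation analysis on GWAS summary statistics. Implements
    instrument selection (significance filtering, greedy LD clumping,
    F-statistic screening), allele harmonization with palindromic-variant
    removal, five causal estimators (fixed- and random-effects inverse-variance
    weighted, MR-Egger, weighted median, simple and weighted mode), sensitivity
    diagnostics (Cochran's Q, MR-Egger intercept, MR-PRESSO, leave-one-out),
    and product-of-coefficients mediation with delta-method standard errors.
    A seeded synthetic GWAS summary-statistics generator with known causal
    structure (including invalid pleiotropic instruments and
    exposure-mediator-outcome triangles) supports end-to-end validation of
    every stage without external data. All user-facing functions take data
    frames and return tibbles.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
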