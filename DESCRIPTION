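Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tidy toolkit for two-sample Mendelian randomization (MR)
    with GWAS summary statistics: instrument selection (p-value threshold,
    greedy LD clumping, palindromic-SNP exclusion, proxy lookup), allele
    harmonization across exposure and outcome tables, instrument-strength
    diagnostics (F statistics, variance explained), univariable estimators
    (Wald ratio, fixed and multiplicative-random-effects inverse-variance
    weighting, MR-Egger, weighted median), Cochran's Q and leave-one-out
    diagnostics, the MR-PRESSO global/outlier/distortion tests with an
    outlier-corrected estimate, multivariable MR for direct effects,
    two-step MR mediation with delta-method standard errors, and a
    binary-outcome power approximation. A synthetic summary-statistics
    generator with known ground truth (causal effect, pleiotropy regime,
    planted outliers, mediator pathway) supports end-to-end testing, and
    run_pipeline() orchestrates the full workflow reproducibly from a
    seeded configuration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
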