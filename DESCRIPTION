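Package: mrkit
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy toolkit for two-sample Mendelian randomization (MR) from
    GWAS summary statistics. Covers the full workflow: reading and validating
    per-SNP association tables, instrument selection (genome-wide significance
    filter, greedy LD clumping, outcome-association and confounder screens,
    proxy substitution, instrument-strength R2/F statistics), allele
    harmonization with palindrome handling, causal-effect estimation
    (inverse-variance weighted with fixed or multiplicative random effects,
    MR-Egger regression with intercept test, weighted median with bootstrap
    standard errors), and a sensitivity suite (modified Cochran's Q,
    leave-one-out, MR-PRESSO global/outlier/distortion tests, funnel and
    forest coordinates). Includes a synthetic two-sample summary-statistic
    generator for calibration and parameter-recovery studies, packaged
    worked-example datasets on smoking quantity and Alzheimer's disease in
    East Asian cohorts, and a configuration-driven pipeline runner.
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
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
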