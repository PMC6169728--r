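Package: genfactor
Title: Polygenic Scores and a General Factor of Childhood Psychopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking polygenic risk scores (PRS) to a general factor of
    childhood psychopathology in twin cohorts. Builds PRS from GWAS summary
    statistics with PLINK-equivalent semantics (standardized betas, MAF/INFO and
    allele-type filters, greedy LD clumping, no-mean-imputation scoring across
    p-value thresholds), estimates polychoric and polyserial correlations with
    influence-function based uncertainty, fits correlated-factors and bifactor
    structural equation models to ordinal symptom items by diagonally weighted
    least squares with latent regressions on PRS and covariates, family-cluster
    sandwich standard errors, robust fit indices, and scaled chi-square
    difference tests, and computes psychometric summaries such as explained
    common variance. A synthetic twin-cohort generator with known ground truth
    supports calibration and parameter-recovery studies.
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
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mvtnorm,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
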