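Package: mrscreen
Title: Two-Sample Mendelian Randomization Screening of GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens GWAS summary statistics for causal relationships with
    two-sample Mendelian randomization. Provides instrument selection
    (p-value thresholding, greedy LD clumping against a reference panel,
    allele harmonization with palindromic-variant handling, and F-statistic
    strength filtering), univariable estimators (Wald ratio, fixed- and
    random-effect inverse-variance weighting, MR-Egger, weighted median)
    with heterogeneity and pleiotropy diagnostics (Cochran's Q, the
    MR-Egger intercept, MR-PRESSO global/outlier/distortion tests, Cook's
    distance), group-wise Benjamini-Hochberg false-discovery-rate control,
    multivariable Mendelian randomization by weighted least squares,
    mediation decomposition with parametric-bootstrap confidence intervals,
    and a synthetic GWAS summary-statistics generator with known causal
    structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
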