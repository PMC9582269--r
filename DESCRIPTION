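Package: summr
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with GWAS
    summary statistics: instrument selection by p-value threshold and
    greedy LD clumping, harmonization of exposure and outcome effect
    estimates to shared effect alleles (strand flips, palindromic
    variants, LD proxies), inverse-variance-weighted estimation under
    multiplicative random effects, simple and weighted median and
    MR-Egger estimators, heterogeneity and directional-pleiotropy
    diagnostics (Cochran Q, I-squared, Egger intercept, MR-PRESSO),
    leave-one-out sensitivity analysis, multivariable MR for direct
    effects, mediation decomposition, Benjamini-Hochberg FDR control,
    and a seeded generator of synthetic two-sample GWAS summary
    statistics for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
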