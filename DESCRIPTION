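Package: bimr
Title: Bidirectional Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomization on
    GWAS summary statistics: instrument selection with significance,
    confounder-exclusion, LD-clumping and F-statistic screens; allele
    harmonization with palindromic-SNP handling; inverse-variance-weighted,
    MR-Egger, weighted-median and mode-based causal estimators; sensitivity
    diagnostics (Cochran's Q and I-squared, Egger intercept, MR-PRESSO global
    and outlier tests, leave-one-out); a bidirectional pipeline with
    Bonferroni significance tiers and table/JSON reports; and a synthetic
    summary-statistic generator with known ground truth for calibration and
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
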