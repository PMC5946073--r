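Package: episyn
Title: Pathway-Based SNP-SNP Interaction Analysis for Case-Control
    Longevity Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting epistatic SNP-SNP interactions in
    candidate-gene case-control panels and following candidate genotype
    combinations into survival. Implements marker-level quality control
    (minor allele frequency, Hardy-Weinberg exact testing in controls,
    r-squared tag pruning), an information-theoretic synergy screen with
    phenotype-permutation significance and Benjamini-Yekutieli false
    discovery rate control, exhaustive multifactor dimensionality
    reduction (MDR) with cross-validation consistency and permutation
    testing, sex-stratified Kaplan-Meier/log-rank/Cox follow-up of
    carrier combinations, and a seeded simulator producing
    pathway-structured genotype studies with planted marginal and
    epistatic effects and genotype-dependent censored survival.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
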