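Package: mrmoloc
Title: Two-Sample Mendelian Randomization and Multiple-Trait
    Colocalization for Cell-Specific Molecular Drivers of Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated analysis framework for nominating cell-specific
    molecular drivers of complex disease from GWAS-style summary statistics.
    Implements conservative (single cis-instrument Wald ratio) and liberal
    (multi-instrument inverse-variance-weighted) two-sample Mendelian
    randomization with leave-one-out, reverse-MR and Steiger directionality
    sensitivity analyses, Bonferroni multiple-testing control, and
    multiple-trait Bayesian colocalization of gene expression, circulating
    protein and disease association signals via Wakefield approximate Bayes
    factors and posterior probabilities of association. A synthetic-data
    module simulates LD-structured genotypes and two-sample GWAS summary
    statistics with controlled causal-variant sharing across traits, so the
    whole framework can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
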