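Package: pqtlmr
Title: Proteome-Wide cis-pQTL Mendelian Randomization for Drug-Target
    Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for proteome-wide drug-target discovery from
    GWAS and pQTL summary statistics: cis-pQTL instrument selection with
    F-statistic and LD-clumping filters, two-sample Mendelian randomization
    estimators (Wald ratio, inverse-variance weighted, MR-Egger, weighted
    median, SMR), Cochran's Q heterogeneity, reverse-MR adjudication,
    single-causal-variant Bayesian colocalization via approximate Bayes
    factors with prior sensitivity analysis, an LD-based horizontal
    pleiotropy scan, evidence tiering, and a single-cell candidate-gene
    expression screen.  Includes a synthetic-cohort generator (multivariate
    normal summary statistics under an LD matrix; negative-binomial
    single-cell counts) so every stage is testable end-to-end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
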