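Package: trfam
Title: Family-Level Analysis of tRNA Fragments in Prenatal Stress Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing serum tRNA fragment (tRF) sequencing data at
    the family level, where a family groups fragments by genome origin
    (nuclear or mitochondrial), parental tRNA amino acid, and cleavage type.
    Implements an exact binomial sign test for directional expression trends
    within families, a simplified negative-binomial Wald differential
    expression stage with median-of-ratios normalisation, fragment
    length-distribution profiling with Kruskal-Wallis family tests, a
    weighted cholinergic target scoring scheme for designating CholinotRFs
    and CholinomiRs, SVM classification of stress status with leave-one-out
    cross-validation and permutation-calibrated significance, and analysis of
    Ellman-assay cholinesterase kinetic traces. A seeded synthetic-cohort
    generator reproduces the statistical structure of maternal/newborn serum
    small-RNA studies so that every stage can be exercised and validated
    without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
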