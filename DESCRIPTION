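Package: cardioscreen
Title: Hypothesis-Free Screening of Claims Codes for Associations with
    Infant Cardiac Malformations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end screening pipeline for detecting maternal and
    paternal claims-code associations with cardiac malformations in
    live-born infants.  Builds pregnancy cohorts from relational claims
    tables (eligibility rules, father linkage, ICD-10 to ICD-9 section
    mapping via General Equivalence Mappings), derives high-dimensional
    exposure-window covariate panels in the high-dimensional propensity
    score tradition, screens every code against the outcome with
    restricted-cubic-spline age adjustment, likelihood-ratio tests,
    Benjamini-Hochberg false discovery rate control and bootstrap
    winner's-curse correction, characterizes selected codes by latent
    semantic analysis (truncated SVD, cosine similarity, agglomerative
    clustering), and discovers high-risk subgroups with Apriori rule
    mining under Westfall-Young permutation control of the family-wise
    error rate.  A synthetic claims-cohort generator with known latent
    structure and planted effect sizes makes every stage testable
    without access to proprietary claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    Rcpp,
    jsonlite,
    splines,
    stats,
    tools,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
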