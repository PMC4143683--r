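Package: famgp
Title: Family-Based Genomic Prediction of Additive Genetic Contributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for whole-genome prediction of
    additive genetic contributions (breeding values) to a repeated-measures
    quantitative trait in multi-generation families. Provides gene-drop
    simulation of family genotypes and phenotypes, the pedigree additive
    relationship matrix, REML fitting of the repeatability animal model,
    minor-allele-frequency stratification with LD pruning and k-means
    collapsing of rare variants into three-level pseudo-markers, GBLUP and
    BayesC-pi whole-genome regression via Gibbs sampling, within-family and
    across-family validation designs, and blending of genomic with
    parent-average predictions.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
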