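Package: ggee
Title: Gene-Gene Eigen-Epistasis Detection with Group-Penalized Regression
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects gene-level epistatic interactions in association studies.
    For every gene pair an interaction variable is built by one of three
    constructions: the Eigen-Epistasis component (the linear combination of
    all pairwise SNP products maximizing squared covariance with the
    phenotype), products of leading principal components, or partial least
    squares components. Gene main-effect groups and gene-pair interaction
    groups then enter a weighted Group Lasso; significance per group is
    assessed by a two-stage screen-and-clean procedure (group lasso screening
    on one data half, group-structured ridge plus permutation tests on the
    other) with Benjamini-Hochberg false discovery rate control. Includes a
    block-LD Hardy-Weinberg genotype simulator and phenotype models for power
    studies, plus readers for PLINK-style raw genotype tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
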