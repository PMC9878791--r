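Package: phenodisc
Title: Discriminative Phenotype Analysis of Mixed-Type Cohort Tables
Version: 0.1.0
Authors@R: person("Pheno", "Disc", email = "maintainer@phenodisc.org",
    role = c("aut", "cre"))
Description: Identifies the qualitative and quantitative variables that best
    discriminate a categorical outcome (genotype, sex, treatment) in
    mixed-type phenotyping tables. Implements mixed-data principal component
    analysis (PCA of quantitative variables unified with multiple
    correspondence analysis of qualitative ones) and multiple factor analysis
    with group weighting, predictive-mean-matching imputation, correlation-
    and variance-contribution-based feature pre-selection, and variable
    importance ranking by four classifiers (binary logistic GLM, multinomial
    log-linear model, elastic net, random forest), together with the
    publication plots and machine-readable tables backing them.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    methods,
    glmnet,
    ggplot2,
    jsonlite,
    readxl,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    ragg
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
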