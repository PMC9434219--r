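Package: phenogp
Title: Genomic and Phenomic Prediction of Growth Traits in Three-Way Hybrid Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative genomic-prediction (SNP-based) versus
    phenomic-prediction (chlorophyll-fluorescence-based) toolkit for
    growth-related traits in segregating three-way hybrid families.
    Provides a synthetic-data generator with known genetic architecture
    (G, E, GxE and residual variance components, tunable trait-endophenotype
    genetic correlations), genotype quality control with mean imputation,
    seven prediction models (ridge, multi-response LASSO, elastic net,
    GBLUP, Bayesian LASSO, multi-trait BayesB, and L2,1-regularized
    multivariate regression with joint sparse precision-matrix estimation)
    behind a common fit/predict contract, repeated nested cross-validation
    over four evaluation settings (within-family, single-condition,
    condition-ahead, cross-family), broad-sense heritability and genetic
    correlation estimation, Hotelling's T2 family comparison, and
    best/worst-line selection-ability scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    vcfR,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
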