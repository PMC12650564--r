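Package: gsae
Title: Genomic Prediction with Autoencoder-Compressed Genotypes
Version: 0.1.0
Authors@R: person("GSAE", "Developers", role = c("aut", "cre"),
    email = "gsae-dev@example.org")
Description: A genomic-selection toolkit for whole-genome marker data that
    compresses high-density SNP genotype matrices with chunked deep
    autoencoders and predicts breeding values from the compressed (or raw)
    features.  Provides genotype input and quality control (call rate,
    minor allele frequency, Hardy-Weinberg filters), one-hot encoding and
    chunking, per-chunk autoencoder training with a compiled Adam
    optimizer, VanRaden and compressed-feature genomic relationship
    matrices, REML variance components and GBLUP mixed-model equations,
    from-scratch Gibbs samplers for BayesA, BayesB, BayesCpi and the
    Bayesian Lasso, seeded machine-learning regressors (SVR, random
    forest, kernel ridge regression, gradient boosting) with leakage-safe
    grid search, repeated k-fold cross-validation metrics (accuracy, bias,
    MSE, MAE), a genotype/phenotype simulator with tunable allele
    frequencies, linkage disequilibrium, family structure and
    heritability, and a file-based pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    quadprog,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    coda,
    testthat (>= 3.0.0),
    VariantAnnotation,
    yaml
Config/testthat/edition: 3
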