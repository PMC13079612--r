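Package: domkit
Title: Dominance-Aware Genomic Prediction for Hybrid Breeding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and benchmarking toolkit for dominance-aware genomic
    prediction in factorial hybrid breeding populations. Provides a stochastic
    simulator of a simple hybrid breeding scheme with controlled dominance
    architectures and heritabilities, the locus-specific weighted
    degree-of-dominance transformation of SNP marker matrices, additive
    (VanRaden), dominance (Vitezica) and combined relationship matrices,
    EMMA-style restricted maximum likelihood estimation with one or several
    genomic kernels (GBLUP), gradient-boosted tree models with Gaussian-process
    Bayesian hyperparameter tuning, a multi-environment trial pipeline
    (outlier removal, two-step BLUEs, marker quality control), and a
    cross-validated model benchmark with ANOVA/Tukey significance testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    lhs,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
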