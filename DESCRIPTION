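Package: halfsibG
Title: Estimation and Comparison of G-Matrices Across Environments from
    Half-Sib Breeding Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evolutionary quantitative genetics of multivariate
    phenotypes measured in paternal half-sib breeding designs replicated
    across environments. Fits the nested sire/dam/block multivariate mixed
    model by Gibbs sampling to obtain posterior distributions of the additive
    genetic covariance matrix (G) in each species-by-environment context;
    compares G-matrices by eigenanalysis, angles between leading eigenvectors
    and the genetic covariance tensor (eigentensors, matrix coordinates, and
    randomization nulls); estimates viability selection gradients from binary
    survival by multiple logistic regression with link-to-probability and
    relative-fitness scaling; and projects plasticity, selection and
    native-phenotype direction vectors through G to quantify the proportion
    of genetic variance available in each direction. Includes a synthetic
    data generator reproducing the full-factorial sire-by-dam block structure,
    environment-specific G (genotype-by-environment interaction),
    trait-dependent survival and pre-measurement mortality, so the entire
    pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'halfsibG-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'core_io.R'
    'gcompare.R'
    'mcmc.R'
    'pipeline.R'
    'selection.R'
    'simdata.R'
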