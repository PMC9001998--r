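Package: gblmm
Title: Grid-Based Bayesian Mixed Models for Longitudinal Genetic Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian variable selection for longitudinal genetic data based on
    mixed models. Jointly models SNP main effects, SNP-SNP (epistatic) and
    SNP-time/environment interactions for traits measured repeatedly at
    irregular, subject-specific time points. Within-subject dependence is
    captured by random effects placed on a small set of grid time points,
    mapped to observation times by linear interpolation, with the grid
    covariance matrix factored by a modified Cholesky decomposition so that
    all variance components admit conjugate normal/half-normal updates.
    Includes an identifiability rank test for the marginal covariance,
    Metropolis-Hastings-within-Gibbs sampling over a composite model space,
    Bayes-factor genome profiles, DIC/BPIC selection of the number of grid
    points, and a simulation engine for longitudinal GWAS designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
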