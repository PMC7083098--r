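Package: idcomp
Title: Estimation and Comparison of Among-Individual Behavioural Covariance Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of animal personality structure from repeated
    open-field-trial measures. Fits multivariate random-intercept mixed models
    by restricted maximum likelihood to estimate species-specific
    among-individual behavioural (co)variance ("ID") matrices, compares the
    matrices by trace difference, leading-eigenvector angle, and Krzanowski
    subspace similarity with parametric-bootstrap confidence intervals, and
    tests for phylogenetic signal in ID dissimilarity using Kendall's tau-b
    with a nested bootstrap over tree and matrix uncertainty. Includes a
    synthetic open-field-trial generator and canonical variate analysis of
    species mean behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
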