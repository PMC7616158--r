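Package: pcgmm
Title: Principal Component GMM for Multivariable cis-Mendelian Randomization
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Robust multivariable cis-Mendelian randomization from GWAS
    summary statistics in a single gene region. Transforms marginal
    variant-trait associations into multivariable regression coefficients on
    the principal components of a weighted genetic correlation matrix, and
    estimates causal effects of several correlated risk factors by a
    continuously-updating generalized method of moments (CUE-GMM) criterion,
    with an overdispersion parameter that corrects standard errors for
    pleiotropic heterogeneity in variant-outcome associations. Provides
    conditional F-statistics for dimension-reduced genetic associations to
    quantify phenotypic heterogeneity, approximate-Bayes-factor
    colocalization with prior sensitivity analysis, Bayesian model averaging
    over risk-factor subsets, and a two-sample summary-data simulator for
    calibration studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
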