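Package: hetvar
Title: Genetic Heterogeneity of Residual Variance in Pedigreed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step restricted maximum likelihood analysis of genetic
    heterogeneity of residual (micro-environmental) variance in pedigreed
    populations. Fits an animal model to the trait with homogeneous or
    sire-family-specific residual variances, then fits a second animal model
    to the log squared estimated residuals to quantify additive genetic
    variance of the residual variance. Includes exact pedigree machinery
    (inbreeding, sparse inverse numerator relationship matrix), a Monte
    Carlo simulator of the multiplicative exponential dispersion model,
    conversion of dispersion estimates to the residual-variance scale
    (evolvability, heritability of residual variance), and a replicated
    simulation study of estimator bias and dispersion-EBV accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
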