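Package: blinar
Title: First-Order Integer-Valued Autoregression with Bell Innovations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling overdispersed count time series with the
    BL-INAR(1) process: a first-order integer-valued autoregression built
    from the binomial thinning operator with Bell-distributed innovations.
    Provides exact Bell-number combinatorics and the one-parameter Bell
    distribution (pmf, cdf, random generation, moments, mean inversion via
    the Lambert W function), process simulation, transition and joint
    probabilities, stationary and multi-step conditional moments, parameter
    estimation by conditional least squares, Yule-Walker and conditional
    maximum likelihood with asymptotic standard errors, model adequacy
    diagnostics (Pearson residuals, Ljung-Box, dispersion-index bootstrap
    test, information criteria), forecasting with holdout evaluation,
    pluggable innovation families for model comparison, and a seeded Monte
    Carlo harness for estimator evaluation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
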