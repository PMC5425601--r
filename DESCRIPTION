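Package: medgroup
Title: Group Differences in Indirect Effects in Two-Group Mediation Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimation and inference for group differences in indirect
    effects and simple (conditional) indirect effects in two-group moderated
    mediation path models. Fits the single-group parameterization (group
    dummy plus X-by-group interaction) and the multi-group parameterization
    (one path model per group, optionally with cross-group equality
    constraints) by Gaussian maximum likelihood, and provides the z test on
    the interaction path, delta-method Wald tests, likelihood ratio tests,
    percentile and bias-corrected bootstrap confidence intervals, and Monte
    Carlo confidence intervals for products of coefficients. Includes a
    seeded simulation engine with the standard two-group population grid for
    studying Type I error, power, coverage, interval width, and miss-side
    balance of the methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
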