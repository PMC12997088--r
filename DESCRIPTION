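Package: srocpb
Title: Publication-Bias Sensitivity Analysis for Diagnostic Meta-Analysis on the SROC Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sensitivity analysis for publication bias in meta-analysis of
    diagnostic test accuracy with sparse 2x2 data. Fits the bivariate binomial
    random-effects model for the summary ROC curve by exact marginal likelihood
    (adaptive Gauss-Hermite quadrature), and adjusts it for selective
    publication with a Copas-type probit selection function acting on a
    per-study t-statistic built from logit sensitivity and logit specificity.
    The selection intercept is profiled out of the conditional-on-publication
    likelihood via a constraint on the marginal selection probability p, which
    is swept as the sensitivity parameter. Includes summary operating point
    and SAUC estimation with delta-method confidence intervals, and a
    simulation engine for selectively published sparse meta-analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    pracma,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
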