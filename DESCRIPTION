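Package: slodrsim
Title: Simulating Disturbance Effects on Spearman's Law of Diminishing Returns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo simulation of a between-person multiplicative
    "disturbance" factor (low motivation, illness, linguistic confusion)
    acting on one-factor cognitive test scores, and of the spurious support
    for Spearman's law of diminishing returns (SLODR) it produces. Implements
    the traditional subgroup paradigm (overlapping ability subgroups, first
    unrotated principal-component saturation) and the contemporary
    latent-variable criteria: maximum-likelihood one-factor confirmatory
    factor analysis, regression-method factor scores, skewness inference,
    individual log residual variance heteroscedasticity, a quadratic latent
    factor with squared-loading constraints, and the likelihood-ratio test,
    together with experiment drivers that tabulate criterion fulfillment
    proportions across disturbance conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    yaml
Config/testthat/edition: 3
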