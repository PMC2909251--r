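Package: comphet
Title: Heterogeneity Tests for Binary Composite Outcomes in Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests for heterogeneity of treatment effect across the components
    of a binary composite outcome in a two-arm trial. Fits four models for the
    correlated component-level binary data (independent logistic regression,
    intracluster-correlation weighted logistic regression with Donald-Donner or
    Rao-Scott weights, population-average logistic regression via generalized
    estimating equations with a robust sandwich covariance, and random-intercept
    logistic regression via adaptive Gauss-Hermite quadrature) and Wald-tests the
    treatment-by-component interaction. Includes a correlated binary simulator
    built from sums of shared Poisson components, deterministic design
    mathematics (component probability solver, continuity-corrected chi-square
    power), and a Monte-Carlo driver that estimates power and type-I error over
    scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    lme4,
    optparse,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
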