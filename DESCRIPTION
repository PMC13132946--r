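Package: twinace
Title: Twin ACE Variance-Component Models for Objective and Self-Evaluated Phenotypes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classical twin-design analysis of continuous phenotypes by
    full-information maximum likelihood (FIML). Fits saturated and ACE/ADE
    structured models to monozygotic and dizygotic twin-pair data, including a
    multivariate correlated-factors model under direct symmetric
    parameterisation, with equality, drop-component and derived-parameter
    constraints, likelihood-ratio tests, AIC, and profile-likelihood
    confidence intervals. Provides the standard assumption ladder on saturated
    models (equality of means, variances and covariances across twin order,
    zygosity and sex), intraclass and cross-twin cross-trait correlations,
    decomposition of phenotypic correlations into genetic and environmental
    contributions, a configurable twin-data simulator, and a pipeline that
    reproduces the full analysis sequence with report output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
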