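Package: swbtwin
Title: Twin-Family Analyses of Subjective Well-Being and Subcortical Brain Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the association between subjective well-being
    and subcortical brain volumes in twin-family cohorts. Provides a synthetic
    twin-cohort generator with monozygotic/dizygotic/sibling structure,
    kinship-structured linear mixed models with linear and quadratic volume
    terms and Satterthwaite denominator degrees of freedom, a post-hoc
    robustness battery, per-study fits pooled by inverse-variance weighted
    least squares, bidirectional two-stage least-squares Mendelian
    randomization with residual-variance strata, multivariate ADE/AE twin
    covariance-structure modeling by maximum likelihood, and univariate and
    bivariate LD-score regression with block-jackknife standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    lme4,
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
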