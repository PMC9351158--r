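Package: zicount
Title: Comparing Poisson, Negative Binomial, and Zero-Inflated Count
    Regression Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing Poisson, negative binomial (NB),
    zero-inflated Poisson (ZIP), and zero-inflated negative binomial
    (ZINB) regression models for count outcomes such as hospital length
    of stay. Provides data generators for all four processes,
    maximum-likelihood fitters with Wald inference and AIC/BIC, a Monte
    Carlo harness that measures convergence rates and mean AIC/BIC/MAE
    over a factorial grid of sample sizes, dispersion levels, and
    structural-zero proportions, and a four-model comparison report for
    empirical length-of-stay-format tables.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    glmmTMB,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
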