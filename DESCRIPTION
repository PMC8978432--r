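Package: bivgap
Title: Analysis of Bivariate Alternating Recurrent Gap-Time Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploratory, nonparametric and semiparametric analysis
    of bivariate alternating recurrent event data, in which subjects cycle
    repeatedly through two states (for example care periods and break periods)
    until censoring. Provides validated long-format data objects, weighted
    product-limit estimation of the joint cumulative distribution of the two
    gap types, the marginal survival of Type I gaps and the conditional
    distribution of Type II given Type I gaps with bootstrap standard errors,
    accelerated failure time regression of both gap types by a smooth
    U-statistic method and a nonsmooth rank-based method with resampling
    variance estimation, a frailty-based scenario simulator, and event-history
    plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
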