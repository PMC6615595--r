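Package: pollardtrend
Title: Abundance Trends from Pollard-Walk Butterfly Monitoring Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Turns weekly Pollard-walk transect counts into species and
    total-abundance trend estimates. Provides degree-day phenology models
    (penalized Poisson splines) to impute missed surveys, trapezoid
    population indices with effort covariates (list-length, projected
    duration), overdispersed Poisson mixed models for log-linear abundance
    trends with parametric-bootstrap intervals and trend classification,
    annual/cumulative rate standardization for cross-scheme comparison,
    and trait association via univariate linear models and phylogenetic
    generalized least squares with maximum-likelihood Pagel's lambda.
    Includes a synthetic monitoring-data generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    mgcv,
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
    nlme,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
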