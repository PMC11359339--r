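Package: phenocast
Title: Hierarchical Prediction of Kiwifruit Flowering Time from Weather and
    Budbreak Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-stage (hierarchical) pipeline for predicting the first
    flowering day of 'Hayward' and 'Zesy002' kiwifruit vines from hourly
    weather records and interval-censored budbreak surveys. Computes growing
    degree days (base 7 C from 1 July), chilling units (hours at or below
    7 C) and daylength; fits per-vine budbreak curves (binomial, Poisson,
    quadratic) selected by AIC and inverts the best fit at 5% budbreak; fits
    and compares candidate flowering-date regressions with stepwise AIC
    refinement, 99% prediction intervals and their empirical coverage,
    year-based train/test evaluation and k-fold cross-validation; includes a
    presence/absence flowering classification baseline (logistic regression
    and random forests) and two-way region-by-cultivar ANOVA summaries. A
    synthetic-data generator emulating the statistical structure of orchard
    phenology surveys makes the whole pipeline testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    lubridate,
    MASS,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
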