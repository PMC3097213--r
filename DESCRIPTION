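Package: agemax
Title: Maximum-Lifespan and Accelerated-Failure-Time Analysis of Immune-Challenge Ageing Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying ageing in insect cohort experiments where an
    early-life immune challenge may shorten life. Implements a maximum-lifespan
    statistic (the 90th percentile of survival time) with exact unconditional
    z-pooled tests for two binomial proportions, accelerated failure time (AFT)
    models with AIC-based distribution selection and time-ratio (c-parameter)
    estimation, a quantile-by-quantile divergence scan of survival curves, and a
    phenoloxidase kinetic-assay pipeline that extracts Vmax from absorbance
    traces and compares groups by one-way ANOVA. A seeded cohort and trace
    simulator with a Tenebrio molitor preset supports testing and power
    analysis when raw data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
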