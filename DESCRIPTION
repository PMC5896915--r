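Package: stormasthma
Title: Seasonal and Episodic Thunderstorm Asthma Admission Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing seasonal and episodic ("thunderstorm")
    asthma hospital admissions from daily time series of admissions,
    weather, pollen and air quality. Provides cyclic-spline estimation of
    the annual admission cycle with generalised cross validation, a
    robust running trimmed-statistics detector for high asthma admissions
    days (HAADs), a roster of eight additive regression model
    specifications with shrinkage-based term selection and a
    population-scaled effect-size convention, replicated train/test
    evaluation of rare-event HAAD classifiers (logistic regression and
    componentwise gradient boosting), seven operational thunderstorm-day
    indicator definitions compared by the Equitable Threat Score, and a
    seeded synthetic-data generator with ground-truth injected admission
    spikes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    rpart,
    geosphere,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
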