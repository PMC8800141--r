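Package: intersim
Title: Simulation Benchmark of Intersection-Specific Prevalence Estimators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating how well statistical and machine-learning
    methods estimate the prevalence of a binary health outcome within social
    intersections (subgroups defined by crossing social position variables,
    e.g. gender by ethnicity by age by income). Provides a synthetic
    data-generating process over 192 intersections with known true
    prevalences, a common fitting interface to nine estimators
    (cross-classification, main-effects/correctly-specified/saturated
    modified Poisson regression with robust variance, multilevel logistic
    MAIHDA, CART, conditional inference trees, CHAID, and random forest),
    accuracy metrics (prevalence-scaled mean absolute deviation, bias and
    variance per intersection), variable-selection summaries, and an
    experiment runner for replicated simulation grids, including an
    NHANES-like blood-pressure demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    rpart,
    ranger,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
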