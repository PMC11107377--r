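Package: diasporaflow
Title: Diaspora-Based Modelling of Migration Intensity and Assortativity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation, simulation and evaluation tools for a hierarchical
    Poisson-multinomial model of international migration in which the size of
    the pre-existing diaspora is the sole covariate. Provides least-squares
    estimators for per-origin arrival rates and a shared pull rate, normal and
    Monte-Carlo confidence bands for forecast arrivals, a constant-rate
    plausibility check for cumulative arrival series, seeded hierarchical flow
    simulation, a population-share gravity baseline, mean-square-error model
    comparison, and a generator of synthetic migration worlds with heavy-tailed
    destination sizes and concentrated (homophilic) diasporas for parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
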