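Package: quitcea
Title: Cost-Effectiveness Analysis of Smoking-Cessation Support with a
    Lifetime Markov Cohort Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the economic evaluation of smoking-cessation
    interventions: within-trial costing and incremental cost-effectiveness
    ratios (per quitter and per QALY from EQ-5D utilities), and a lifetime
    Markov cohort model of smoking, quitting and relapse with cardiovascular
    disease and lung-cancer states (tunnel states for time since diagnosis,
    time-since-quit risk decay), annual cycles and discounting. Includes
    method-of-moments parameter distributions (beta, gamma, lognormal),
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves, one-way sensitivity analysis, scenario analysis, a synthetic-data
    generator for age-sex rate curves and individual-level trial records, and
    broom-style tidiers plus ggplot2 visualisations for all result types.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
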