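Package: aprt
Title: Simulation, Scoring and Factorial Analysis of a Tri-Outcome Physical
    Risk-Taking Task
Version: 0.1.0
Authors@R:
    person("APRT", "Maintainers", email = "aprt@example.org", role = c("aut", "cre"))
Description: A scriptable engine for a 64-trial, five-factor physical
    risk-taking task with three press outcomes (reward, neutral, injury),
    health and points bookkeeping, death and quit semantics, and an enforced
    inter-press delay ("cool") mode. Includes parameterized simulated agents
    with heterogeneous risk propensity, injury-cue sensitivity and
    satisficing targets; a synthetic cohort generator with trait-correlated
    self-report scale scores; difference-score psychometrics with Cronbach's
    alpha; and the full statistical pipeline: Winsorizing, log transforms,
    within-subject factorial marginal models with robust Wald tests,
    Holm-Sidak step-down correction, post hoc interaction decomposition and
    family-wise correlation screens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
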