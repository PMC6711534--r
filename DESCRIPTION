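Package: oedmicro
Title: Optimal Experiment Design and In-Silico Precision Analysis for
    Dynamic Microbial Inactivation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to evaluate and optimize sampling schedules for
    parameter estimation in dynamic (non-isothermal) microbial
    inactivation experiments described by the Bigelow model. Provides
    closed-form survival predictions and local parameter sensitivity
    functions under piecewise-linear temperature profiles, Fisher
    information matrices with a D-optimality criterion and a
    minimum-spacing barrier penalty, a seeded population-based global
    optimizer for sampling times, Monte Carlo simulation of noisy
    experiments with nonlinear least-squares refitting to predict
    parameter precision, and uniform-versus-optimal design comparison
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
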