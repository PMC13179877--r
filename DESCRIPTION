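Package: pkmoo
Title: Single- and Multi-Objective Genetic Search for Population
    Pharmacokinetic Model Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated population pharmacokinetic (popPK) model selection
    over token-set search spaces encoded as binary genomes.  Provides a
    lightweight nonlinear mixed-effects evaluator (analytic 1-3 compartment
    predictions, FOCE-with-interaction-style approximate marginal
    likelihood, covariance-based diagnostics), a penalized single-objective
    hybrid genetic algorithm with one- and two-bit steepest-descent
    downhill search, an NSGA-II multi-objective search over objective
    function value and number of estimated parameters with Pareto-front
    archiving and effect-limit sampling, synthetic dataset generation for
    rich and sparse sampling designs, and prediction-corrected visual
    predictive checks for subjective comparison of non-dominated models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
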