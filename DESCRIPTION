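Package: daive
Title: Decision Analysis for Intervention Value Efficiency in Factorial Optimization Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting an optimized multicomponent intervention from a
    2^k factorial optimization trial with several valued outcomes, following the
    decision analysis for intervention value efficiency (DAIVE) approach used in
    the multiphase optimization strategy (MOST). Fits a saturated Bayesian
    factorial ANOVA per outcome with independent normal coefficient priors via a
    conditionally conjugate Gibbs sampler, computes posterior expected outcomes
    for every candidate factor-level combination, scales outcomes to a common
    0-1 range, combines them with a swing-weighted linear value function, selects
    the value-maximizing combination, and probes robustness of that decision by
    systematically varying the outcome weights. Includes a synthetic trial
    generator with known ground truth (including item-level instrument
    responses) and scoring utilities for belief, knowledge and satisfaction
    instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
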