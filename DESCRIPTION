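Package: coolmediate
Title: Principal-Strata Mediation Analysis for Cooling-Off Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of total and emotion-mediated treatment effects in
    four-arm randomized experiments that manipulate a short-lived mediator
    with a randomized cooling-off period. Implements the principal-strata
    (complier/always-taker/never-taker) plug-in estimator of the mediated
    effect, bootstrap percentile inference with pre-registered decision
    rules and an economic-significance threshold, outcome-neutral validity
    gates (scale reliability, manipulation strength, attrition, filler-effect
    checks), a simulation-based power and sample-size planner, exploratory
    decompositions (mediated share, per-emotion and per-option contrasts,
    extensive margin), aggregation of expert forecasts, and a synthetic
    four-arm experiment generator with known true estimands for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
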