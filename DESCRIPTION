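Package: melcea
Title: Multistate Cost-Effectiveness Analysis of Sequential Advanced-Melanoma Treatment Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level cost-effectiveness analysis of sequential treatment
    strategies for advanced melanoma, built around a three-state multistate
    model (first line, subsequent lines, death). Provides a seeded synthetic
    cohort generator with confounded treatment assignment, inverse probability
    of treatment weighting via gradient-boosted propensity scores with
    balance-optimal iteration selection, weighted Kaplan-Meier transition
    estimation with parametric tail extrapolation, discounted cost and QALY
    accumulation over monthly cycles, efficiency-frontier and incremental
    cost-effectiveness ratio computation, non-parametric bootstrap confidence
    intervals and cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    flexsurv,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
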