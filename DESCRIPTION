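Package: cmrctsim
Title: Simulation of Cluster Cohort-Multiple Randomised Controlled Trials
    with Risk-Correlated Treatment Refusal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates cluster-randomised trials embedded in a standing
    cohort (the cluster cmRCT design) in which patients and clinicians may
    refuse an offered intervention, with refusal probabilities linearly
    correlated with each patient's underlying event risk.  Event and
    mortality times are Weibull with shared individual- and cluster-level
    normal random effects on the log-hazard scale, giving informative
    censoring by death and administrative censoring at the end of
    follow-up.  Each simulated trial can be analysed by intention to
    treat, per protocol, and the two-stage instrumental-variable
    estimators 2SPS (predictor substitution) and 2SRI (residual
    inclusion), each on top of a marginal (robust), lognormal-frailty, or
    gamma-frailty Cox proportional-hazards model.  A replication engine
    computes percentage bias, empirical standard errors and power across
    scenario grids, and a simulation-based search determines the number
    of clusters needed for a target power with or without an assumed
    refusal rate factored in.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    ggplot2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
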