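Package: snbsurv
Title: Self-Normalizing Balanced Counterfactual Survival Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates individual treatment effects for right-censored survival
    data with a self-normalizing balanced survival network (SNB): a shared
    SELU representation network balanced across treatment arms with a debiased
    Sinkhorn (entropic p-Wasserstein) penalty, two arm-specific Cox risk
    networks, Breslow baseline hazards, and a time-at-risk (TaR) treatment
    effect defined as the difference in time to 90% predicted mortality
    between counterfactual arms. Includes a confounded Weibull
    proportional-hazards cohort simulator with analytically known effects, a
    T-learner Cox baseline, and a recommendation-evaluation suite
    (consistency grouping, inverse probability of treatment weighting,
    weighted Kaplan-Meier and log-rank, multivariate Cox hazard ratios, risk
    differences, restricted mean survival time differences, and IPCW
    integrated Brier scores).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    arrow
Config/testthat/edition: 3
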