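Package: samgsd
Title: Self-Adapting Mixture Priors in Bayesian Group-Sequential
    Noninferiority Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Design and simulation of Bayesian group-sequential
    noninferiority trials with a binary endpoint that borrow historical
    control information through a Self-Adapting Mixture (SAM) prior.
    Provides meta-analytic-predictive (MAP) prior elicitation from
    aggregated historical studies via a hierarchical binomial model,
    expectation-maximization approximation of the MAP prior as a beta
    mixture, likelihood-ratio congruence weighting of the informative
    component, effective sample size by the expected local information
    ratio (ELIR), Hwang-Shih-DeCani error-spending group-sequential
    boundaries computed by recursive numerical integration with their
    mapping to posterior-probability decision thresholds, and a Monte
    Carlo engine for operating characteristics (type I error, power,
    expected enrollment) under congruent and incongruent scenarios with
    ESS-driven adaptive allocation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    coda,
    jsonlite,
    metafor,
    rjags,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
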