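Package: wtrack
Title: Reinforcement-Learning Models of W-Track Spatial Alternation Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits actor-critic REINFORCE agents learning the
    three-arm W-track spatial alternation task. Provides the task environment
    (reward-delivery algorithm, 13-state space, inbound/outbound trial
    classification), a family of policy-gradient agents with perfect one-step
    memory and optional dynamic spatial preferences (independent arm
    preference and neighbor-transition preference), behavioral analyses
    (Gaussian-smoothed learning curves, inbound/outbound error curves,
    exponential fits with 99 percent confidence intervals), parameter
    estimation by seeded simulated annealing over common-random-number
    ensembles, and a synthetic-cohort generator producing rat-like visit logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
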