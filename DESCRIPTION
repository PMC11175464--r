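Package: surprisemin
Title: Surprise-Minimization Arbitration Models for Multiple-Bandits Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of structural credit
    assignment in multiple-bandits tasks, where an agent makes two decisions
    per trial and must infer the hidden mapping between decisions and
    color-coded outcomes. Implements a hierarchical reinforcement-learning
    model that arbitrates between candidate decision-outcome mappings by
    accumulating the difference in surprise (absolute prediction error)
    between policies, together with fixed-weight and joint-action competitor
    models. Provides the anti-correlated Gaussian random-walk task
    environment, maximum-a-posteriori model fitting with empirical priors,
    random-effects Bayesian model selection via exceedance probabilities,
    win-stay/lose-shift behavioral analyses, and model-based single-trial
    EEG regression with cluster-based permutation tests, including a
    synthetic-epochs generator with planted effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
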