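Package: critlearn
Title: Observer Models of Criterion Learning Under Changing Category Probability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and fitting of trial-level observer models for
    orientation-categorization tasks in which the prior probability of a
    category changes at hidden change points. Provides a generative task
    model (sample-and-hold category probability, Gaussian categories,
    sensory and criterion-adjustment noise), a family of Bayesian
    change-point detection observers with a joint posterior over run
    length and pre-change state, heuristic alternatives (fixed criterion,
    exponential averaging with and without a conservative bias, a
    mixture-of-delta-rules approximation, reinforcement learning of the
    criterion, and a volatility-tracking Bayesian learner), task-specific
    likelihoods for covert-choice and overt-criterion responses,
    grid-based Bayesian fitting with marginal likelihoods, maximum
    likelihood with AIC/BIC, fixed- and random-effects model comparison
    with protected exceedance probabilities, and parameter- and
    model-recovery diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
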