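Package: huntswitch
Title: Computational Analysis of Switching Between Hunting and Escaping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a two-dimensional pursuit-evasion arena task in which a
    player alternates between hunting a fleeing prey and escaping a pursuing
    predator, and implements the computational analysis of that behavior:
    three generative softmax action-selection models of player movement
    (reactive, fixed one-step predictive, and variable-timescale predictive
    with momentum), sliding-window maximum-likelihood fitting with BIC and
    random-effects Bayesian model selection (protected exceedance
    probabilities), SVM decoding of the task condition from fitted parameters
    with a calibrated condition-specific state (Cp), trajectory metrics
    (thigmotaxis, linearity, movement variability), and mixed-model analyses
    of state transitions after task switching. A synthetic-cohort generator
    reproduces the statistical structure the analysis assumes so the full
    pipeline runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
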