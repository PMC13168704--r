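Package: beadsampler
Title: Computational Modelling of Costly Information Sampling in the Bead Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sequential information sampling in the
    child-friendly "bead" (island/animal) task. Provides closed-form task
    mathematics (probability of a correct majority judgment, expected gain,
    optimal sample number, sampling efficiency and signed deviation), six
    logistic stopping-rule models with leaky (decayed) evidence accumulation,
    hierarchical Bayesian fitting with an adaptive MCMC sampler and a
    non-centered parameterization, PSIS-LOO model comparison with Pseudo-BMA+
    weights, posterior predictive checks, simulation-based calibration, a
    synthetic-cohort generator, behavioural outcome summaries with mixed-model
    group contrasts, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    lme4,
    lmerTest,
    emmeans
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
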