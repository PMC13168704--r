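# beadsampler

Computational modelling of costly information sampling in the child-friendly
"bead" task, for researchers in computational psychiatry and developmental
decision science.

In the task, a participant may sample up to 20 animals (dogs/cats) from a
hidden island before judging which of two islands they are on. A correct
judgment earns 100 credits, each sample costs `c ∈ {0, 1, 4}` credits, and
the predominant animal appears with probability `q ∈ {0.6, 0.8}`. The
interesting behaviour is *when people stop sampling*: the expected gain

&nbsp;&nbsp;&nbsp;&nbsp;E[Gain | n, q, c] = (100 − n·c) · p(n | q),
&nbsp;&nbsp;p(n | q) = P(strict majority correct) + ½·P(tie),

first rises and then falls with `n`, so efficient sampling balances
information against cost. The package provides:

* **Task mathematics** — `correct_prob()`, `expected_gain()`,
  `optimal_n()`, `efficiency()`, `signed_deviation()` (exact binomial
  sums, smallest-`n` tie-breaking).
* **Six stopping models** — per-decision logistic hazards over cost- and
  evidence-related decision variables, including leaky evidence
  accumulation `CI_j = α·CI_(j−1) ± 1` and two-stage "second-thought"
  variants (`beads_model()`, `stop_prob()`, `trial_loglik()`,
  `stopping_distribution()`).
* **Hierarchical Bayesian fitting** — non-centered hierarchy, weakly
  informative priors, an adaptive-Metropolis-with-interweaving sampler in
  C++, split-R̂/ESS diagnostics (`fit_hierarchical()`).
* **Model comparison** — in-package PSIS-LOO and Pseudo-BMA+ weights,
  posterior predictive checks (`compare_models()`,
  `posterior_predictive()`).
* **Simulation-based calibration** — rank statistics with formal
  uniformity tests, conjugate-toy and full-pipeline variants
  (`run_sbc()`, `run_sbc_toy()`, `uniformity_check()`).
* **Synthetic cohorts** — the 6-condition block design, Bernoulli stimulus
  sequences, model agents, NT-like and ASD-like generating parameter sets
  (`make_cohort()`, `default_group_params()`, `sweep_parameter()`).
* **Behavioural statistics** — per-child condition summaries, mixed-model
  group contrasts via `lmerTest`/`emmeans`, FDR-adjusted
  parameter–behaviour correlations (`summarize_children()`,
  `fit_group_contrasts()`, `correlate_params_behavior()`).

See `vignettes/beadsampler-methods.Rmd` for the full model account and the
design decisions.

## Worked example

```r
library(beadsampler)

# Where should one stop at q = 0.8, c = 4?
gp <- gain_profile(0.8, 4)
round(gp[2:6, ], 3)
#>   n p_correct expected_gain
#> 2 1     0.800        76.800
#> 3 2     0.800        73.600
#> 4 3     0.896        78.848
#> 5 4     0.896        75.264
#> 6 5     0.942        75.366
attr(gp, "optimal_n")     # 3 samples maximise the expected gain
#> [1] 3
efficiency(10, 0.8, 4)    # oversampling to 10 forfeits a quarter of it
#> [1] 0.7464179

# Simulate a small neurotypical-like cohort and summarise behaviour
coh <- make_cohort("CostEvidence", default_group_params("NT"), 8, seed = 1)
s <- summarize_children(coh$trials)
head(s[, c("participant_id", "cost_level", "evidence_level",
           "mean_samples", "mean_efficiency", "sampling_variation")], 4)
#>   participant_id cost_level evidence_level mean_samples mean_efficiency
#> 1           S001       high           high         2.31           0.893
#> 2           S001       high            low         4.50           0.901
#> 3           S001        low           high         6.88           0.979
#> 4           S001        low            low        10.81           0.976
#>   sampling_variation
#> 1               1.70
#> 2               3.22
#> 3               2.60
#> 4               5.23

# Refit the generating model hierarchically (desk preset)
fit <- fit_hierarchical("CostEvidence", coh$trials,
                        mcmc = mcmc_preset("desk"), seed = 2)
fit
#> Hierarchical fit of model CostEvidence
#>   8 children, 768 trials; 2 chains x 2000 draws (+2000 warmup)
#>   retained draws per parameter: 4000
#>   convergence pass: FALSE (max split R-hat 1.344)
extract_group_summary(fit, "beta_draw")
#> $median
#> [1] 0.104        # true generating group mean: 0.12
#> $hdi
#> [1] 0.059 0.152
extract_group_summary(fit, "alpha_decay", scale = "natural")
#> $median
#> [1] 0.943        # true generating value: 0.9
#> $hdi
#> [1] 0.862 0.996
```

The flagged convergence is the diagnostics doing their job at this small
scale: a handful of weakly identified group SDs mix slowly under the desk
preset (group means and child-level parameters are well resolved, as the
summaries show); the `full` preset — 4 chains × 10,000 draws, i.e. 40,000
retained draws per parameter — is the study-scale remedy.

A command-line surface wraps the same functions:

```sh
Rscript inst/cli/beads.R simulate --children 10 --seed 1 --out cohort.csv
Rscript inst/cli/beads.R metrics  --data cohort.csv --out summaries.csv
Rscript inst/cli/beads.R profile  --out profiles.csv
```

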