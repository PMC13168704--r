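---
title: "Modelling costly information sampling in the bead task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling costly information sampling in the bead task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`beadsampler` analyses sequential information sampling in a child-friendly
bead task: on each trial the participant may sample up to 20 animals (dogs
and cats) from a hidden island and then judge which of two islands they are
on. A correct judgment earns 100 credits; each sample costs `c` credits
(0, 1 or 4 by condition), and the predominant animal appears with
probability `q` (0.6 or 0.8 by condition). The package covers the task's
closed-form optimality mathematics, six stopping-rule models, hierarchical
Bayesian estimation, model comparison, simulation-based calibration, a
synthetic-cohort generator and the behavioural statistics around them.

## Task mathematics

A judgment after `n` samples follows the majority animal, with a fair coin
on ties, so the probability of being correct is

$$p(n \mid q) = P(\text{strict majority correct}) + \tfrac12 P(\text{tie}),
\qquad p(0 \mid q) = \tfrac12,$$

computed by exact binomial summation (`correct_prob()`; `n` is at most 20,
so no approximation is needed or used). The expected gain is
$\mathbb{E}[\text{Gain} \mid n,q,c] = (100 - nc)\,p(n\mid q)$ and the
optimal sample number maximises it over `n` in 0..20. Two numerical
conventions matter:

* **Even-`n` ties.** Even sample numbers add a tie term weighted by 1/2;
  this yields the parity identity $p(2k) = p(2k-1)$, which the test suite
  verifies against exhaustive enumeration of all $2^n$ outcomes.
* **Argmax ties.** At `c = 0` the gain at `n = 19` and `n = 20` is equal by
  the parity identity; `optimal_n()` returns the smaller `n`, since fewer
  samples weakly dominate at equal gain.

Sampling efficiency divides the expected gain at the observed sample count
by the maximum expected gain; signed deviation is the observed minus the
optimal count. Both are defined trial-wise and reused unchanged by the
behavioural-summary module (single source of truth).

## The six stopping models

At each decision point $j = 0..19$ (after seeing $j$ animals — a decision
exists at $j = 0$ because judging without sampling is allowed) the
probability of stopping is a logistic function of decision variables (DVs):

$$p_{ij} = \mathrm{logit}^{-1}\!\Big(\sum_k \beta_k\, DV_{ijk}\Big).$$

Cost-related DVs: intercept, low/high-cost condition dummies (zero-cost is
the reference), samples drawn $j$, cumulative cost $c\,j$. Evidence-related
DVs: unit log evidence $\ln\frac{q}{1-q}$, the absolute decayed cumulative
information $|CI_{ij}|$, their product (total log evidence), and the
previous trial's sample number and correctness (+1/-1). Cumulative
information follows a leaky count difference,

$$CI_{i0} = 0,\qquad CI_{ij} = \alpha\, CI_{i,j-1} \pm 1$$

(+1 dog, -1 cat), so $\alpha = 1$ keeps all evidence equally and
$\alpha = 0$ keeps only the newest sample. The two one-stage models are
`CostOnly` (cost DVs) and `CostEvidence` (cost plus evidence DVs with a
shared intercept). The four two-stage models give each stage its own
intercept and DV family (cost-first or evidence-first) and pass a declined
first-stage stop through a second thought with probability $p^{sec}$:

$$p_{ij} = p^{(1)}_{ij} + \big(1 - p^{(1)}_{ij}\big)\, p^{sec}\, p^{(2)}_{ij},$$

where $p^{sec}$ is indexed either by the three cost conditions or the two
evidence conditions. Sampling is forced to stop at $j = 20$, which
contributes no probability factor to the likelihood; a trial with `n`
samples contributes $\sum_{j<n} \log(1-p_j) + \log p_n$ (continuations
only, for `n = 20`).

Conventions where the design was open:

* At the first trial (and only there) the previous-trial DVs are 0; the
  carry-over then runs across block boundaries, since trials are
  consecutive in experiment time.
* DVs enter raw, not z-scored; coefficients are therefore on interpretable
  task units (credits, samples, nats).
* CI resets to 0 at each trial start; decay acts within a trial only.

## Hierarchical estimation

Child-level parameters are normal around group-level means on an
unconstrained scale: identity for the $\beta$s, log-odds for
$\alpha_{Decay}$ and the $p^{sec}$s. Default priors are weakly informative
— group means $\mathcal N(0, 2)$, group SDs half-$\mathcal N(1)$ — and the
child level uses the non-centered construction (standard-normal latents
scaled by the group SD). Groups are always fitted separately; nothing is
shared across groups.

Sampling uses a blockwise adaptive Metropolis scheme written for this model
family and implemented in C++: one multivariate random-walk block per child
(latents), one for the group means and one for the log group SDs, each with
Robbins–Monro scale adaptation toward 25% acceptance and a running-covariance
preconditioner refreshed during warm-up; plus, every iteration, four sweeps
of likelihood-invariant interweaving moves (translating a group mean against
its latents, and rescaling a group SD against its latents) that decouple the
hierarchical funnel at no likelihood cost. Adaptation freezes at the end of
warm-up, so the retained draws target the exact posterior. Convergence is
assessed by split-$\hat R$ (threshold 1.01) and Geyer-style effective sample
sizes; a non-converged fit is flagged, never silently returned. The
random-walk kernel has no divergent transitions, so the divergence count in
the diagnostics is structurally zero.

Two presets are provided. `full` reproduces the study-scale settings: 4
chains, 5000 warm-up and 10,000 retained iterations each, i.e. 40,000
retained draws per parameter. `desk` (2 chains, 2000/2000) is the
interactive/testing scale; a random-walk kernel needs more iterations than
a gradient-based one for comparable mixing, which is why the desk preset is
not smaller. Weakly identified group SDs can still show $\hat R$ above the
threshold at desk scale — the flag is informative, and the full preset is
the remedy. End-to-end correctness of the sampler is checked by
simulation-based calibration on the real model (prior draws, simulated
cohorts, refits, rank uniformity), not only by parameter recovery.

## Model comparison and posterior predictive checks

Out-of-sample fit is estimated leave-one-trial-out by PSIS-LOO: importance
ratios per trial are tail-smoothed with a generalized Pareto fit
(Zhang–Stephens profile estimator with the usual weak prior on the shape);
shapes above 0.7 flag unreliable trials. Model weights come from
pseudo-Bayesian model averaging with Bayesian-bootstrap regularisation
(Pseudo-BMA+, 1000 Dirichlet replicates by default, seeded). Comparison is
always within one group on the identical dataset, which `compare_models()`
asserts. Posterior predictive checks average the analytic stopping-time
distribution of every trial — using the full 20-symbol sequence, including
animals the participant never saw — over posterior draws, and tabulate the
predicted $P(N = n)$ curves against observed histograms per group and
condition.

## Simulation-based calibration

`run_sbc()` draws group-level parameters from the priors, simulates a
cohort, refits it, and records the rank of each true group-level mean among
`D` thinned posterior draws; uniform ranks over 0..D indicate calibrated
inference. Because visual inspection does not scale, uniformity is tested
formally: a chi-square goodness-of-fit over 20 rank bins plus an
approximate simultaneous ECDF band (pointwise binomial bands at a
Sidak-adjusted level). The conjugate toy (`run_sbc_toy()`, a normal mean
with known variance and analytic posterior) calibrates the rank machinery
itself and, with a deliberately mis-scaled posterior, demonstrates that the
test rejects broken inference. Paper-scale settings are `N = 1000`
replicates with `D = 400` draws from two chains thinned by 10
(`sbc_full_settings()`); desk-scale runs use `N = 50` on the toy and
miniature cohorts on the real model.

## The synthetic-cohort generator

`make_cohort()` replaces the study's child data. It emulates: the 6-block
design (3 cost levels crossed with 2 evidence levels, cost-block order
permuted per seed, evidence mini-blocks shuffled within cost blocks), 16
trials per mini-block (96 trials; 8 per mini-block gives the 48-trial short
form used by children who found the task long), i.i.d. Bernoulli(`q`)
stimulus sequences of fixed length 20 (sampling with replacement — the
islands' ratios do not deplete), agents whose stopping follows any of the
six models, majority judgments with fair-coin ties (the same rule the
correctness mathematics presupposes), and credit bookkeeping
(`credits = 100·correct − c·n`).

The default generating parameter sets (`default_group_params()`) encode two
phenotypes chosen once to reproduce the study-level behavioural profile:
an NT-like group (moderate baseline stopping, strong sensitivity to
accumulating samples/costs/evidence, negative last-trial carry-over,
near-uniform evidence weighting, $\alpha \approx 0.9$) and an ASD-like
group (weaker baseline stopping at zero cost, larger nominal-cost offsets,
weaker dynamic sensitivities, negligible carry-over, recency-weighted
evidence, $\alpha \approx 0.55$). Under these defaults the simulated groups
show the qualitative signatures of interest: more zero-cost sampling and
higher costly-condition sampling variation in the ASD-like group, and lower
overall efficiency. The generator does **not** emulate reaction times,
gaze, attentional lapses, within-session learning beyond the modelled
last-trial carry-over, or any departure from the stopping models
themselves — so passing tests certify the pipeline's internal consistency
on model-generated data, not the models' adequacy for real children.

## Behavioural statistics

`summarize_children()` produces the per-child-by-condition outcomes (mean
samples, credits, accuracy, mean efficiency, mean signed deviation, and
sampling variation as the inter-trial SD; cells with fewer than two trials
get an undefined variation and are excluded from its model rather than
imputed). Group contrasts delegate to the standard mixed-model stack:
`lmerTest` (Satterthwaite degrees of freedom) with
`outcome ~ group * cost * evidence` and a per-child random intercept — the
parsimonious structure supported by one observation per child and cell —
falling back to a fixed-effects fit when the random intercept is singular,
with the simplification recorded. Estimated marginal means and group
contrasts (overall and within cost levels) come from `emmeans` with
single-step multivariate-t adjustment. Parameter–behaviour associations use
Spearman correlations with Benjamini–Hochberg FDR adjustment (the generic
"false discovery rate" choice).

## Problem sizes and runtime choices

The test suite and the acceptance script run at deliberately modest sizes
chosen as this package's own desk scale: 40-child cohorts for parameter
recovery; 12-child, 48-trial cohorts and 10 seeded replicates per direction
for model recovery; `N = 50` toy SBC replicates; 10,000 replicate trials
for the simulator-versus-analytic check. These sizes keep every check
well-resolved (Monte-Carlo error comfortably inside the asserted margins)
while completing in minutes on a single core.

## Known limitations

* The sampler is a random-walk scheme: robust and exactly targeted, but
  slower-mixing than gradient-based samplers; weakly identified group SDs
  may need the full preset to pass the 1.01 threshold.
* PSIS-LOO is leave-one-trial-out; trials within a child are conditionally
  dependent through the carry-over DVs, so leave-one-child-out would be a
  stricter (and much costlier) alternative.
* The two-stage models' stage-specific DV assignments follow the
  cost/evidence taxonomy with per-stage intercepts; alternative
  assignments would need only a registry change.
* Efficiency for `n = 0` uses $p = \tfrac12$ exactly, the literal
  continuation of the correctness formula.
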