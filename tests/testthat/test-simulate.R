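test_that("designs cover each condition once, in seeded block order", {
  d <- make_design(16L, seed = 1)
  expect_equal(nrow(d), 96)
  cells <- unique(d[, c("cost_level", "evidence_level")])
  expect_equal(nrow(cells), 6)
  expect_equal(as.integer(table(d$block_index)), rep(16L, 6))
  short <- make_design(8L, seed = 1)
  expect_equal(nrow(short), 48)
  expect_identical(make_design(16L, seed = 5), make_design(16L, seed = 5))
  expect_error(make_design(0L), "trials_per_miniblock")
})

test_that("stimulus sequences are 20 i.i.d. draws of the predominant animal", {
  expect_equal(gen_stimuli(1 - 1e-12, "dog", seed = 1), strrep("D", 20))
  expect_equal(gen_stimuli(1 - 1e-12, "cat", seed = 1), strrep("C", 20))
  expect_identical(gen_stimuli(0.8, "dog", seed = 3),
                   gen_stimuli(0.8, "dog", seed = 3))
  withr::local_seed(11)
  counts <- vapply(1:4000, function(i) {
    s <- gen_stimuli(0.8, "dog")
    sum(strsplit(s, "")[[1]] == "D")
  }, numeric(1))
  se <- sqrt(20 * 0.8 * 0.2 / 4000)  # SE of the mean predominant count
  expect_lt(abs(mean(counts) - 16), 3 * se)
})

test_that("agent extremes behave as forced limits", {
  m <- beads_model("CostOnly")
  trials <- generate_trials(make_design(4L, seed = 2), seed = 2)
  stopper <- stats::setNames(c(60, 0, 0, 0, 0), m$par_names)
  sim <- simulate_agent(m, stopper, trials, seed = 3)
  expect_true(all(sim$n_samples == 0))
  expect_lt(abs(mean(sim$correct) - 0.5), 0.25)  # coin-flip judgments
  never <- stats::setNames(c(-60, 0, 0, 0, 0), m$par_names)
  sim2 <- simulate_agent(m, never, trials, seed = 3)
  expect_true(all(sim2$n_samples == 20))
})

test_that("credits bookkeeping holds on every simulated trial", {
  coh <- make_cohort("CostEvidence", default_group_params("ASD"), 5, seed = 9)
  with(coh$trials, expect_true(all((credits + c * n_samples) %in% c(0, 100))))
  expect_true(all(nchar(coh$trials$stimuli) == 20))
  # majority judgment consistent with seen samples (no-tie trials)
  tr <- coh$trials
  seen <- vapply(seq_len(nrow(tr)), function(i) {
    s <- stimuli_to_signed(tr$stimuli[i])
    n <- tr$n_samples[i]
    if (n == 0) 0L else sum(s[seq_len(n)])
  }, integer(1))
  decided <- seen != 0
  expect_true(all(tr$choice[decided] == ifelse(seen[decided] > 0, "dog", "cat")))
})

test_that("cohorts replay bitwise under a fixed seed and respect group SDs", {
  a <- make_cohort("CostEvidence", default_group_params("NT"), 4, seed = 21)
  b <- make_cohort("CostEvidence", default_group_params("NT"), 4, seed = 21)
  expect_identical(a$trials, b$trials)
  expect_identical(a$params, b$params)
  gl0 <- default_group_params("NT")
  gl0$sd[] <- 0
  c0 <- make_cohort("CostEvidence", gl0, 3, seed = 4)
  expect_equal(c0$params[1, ], c0$params[2, ])
  expect_equal(c0$params[2, ], c0$params[3, ])
})

test_that("cohort parameter draws match their group-level normals", {
  gl <- default_group_params("NT")
  coh <- make_cohort("CostEvidence", gl, 200, seed = 31,
                     trials_per_miniblock = 1)
  for (p in c("beta_0", "beta_draw", "alpha_decay")) {
    se <- gl$sd[p] / sqrt(200)
    expect_lt(abs(mean(coh$params_unconstrained[, p]) - gl$mean[p]), 3.5 * se)
  }
})

test_that("simulated stopping matches the analytic distribution", {
  # single fixed sequence, history-free parameters, 10,000 replicate trials
  m <- beads_model("CostEvidence")
  pars <- nt_point_params()
  pars[c("beta_last_draw", "beta_last_correct")] <- 0
  cond <- beads_condition("low", "high")
  stim <- gen_stimuli(0.8, "dog", seed = 17)
  analytic <- stopping_distribution(m, pars, stim, cond)
  trials <- data.frame(
    cost_level = "low", evidence_level = "high", true_island = "dog",
    stimuli = stim, stringsAsFactors = FALSE
  )[rep(1, 10000), ]
  sim <- simulate_agent(m, pars, trials, seed = 18)
  emp <- tabulate(sim$n_samples + 1L, nbins = 21) / nrow(sim)
  tv <- 0.5 * sum(abs(emp - analytic))
  expect_lt(tv, 0.02)
})

test_that("parameter sweeps report per-condition metrics over the grid", {
  m <- beads_model("CostEvidence")
  base <- nt_point_params()
  trials <- generate_trials(make_design(4L, seed = 5), seed = 5)
  sw <- sweep_parameter(m, base, "beta_last_draw", c(-0.2, 0), trials,
                        n_reps = 4, seed = 6)
  expect_equal(nrow(sw), 2 * 6)
  expect_setequal(unique(sw$value), c(-0.2, 0))
  expect_true(all(sw$mean_efficiency > 0 & sw$mean_efficiency <= 1))
  expect_error(
    sweep_parameter(m, base, "not_a_parameter", 0, trials, n_reps = 1),
    "unknown parameter")
})

test_that("stronger last-trial carry-over reduces sampling variation", {
  m <- beads_model("CostEvidence")
  base <- nt_point_params()
  trials <- generate_trials(make_design(16L, seed = 8), seed = 8)
  sw <- sweep_parameter(m, base, "beta_last_draw", c(-0.25, 0), trials,
                        n_reps = 25, seed = 9)
  agg <- tapply(sw$sampling_variation, sw$value, mean)
  expect_lt(agg[["-0.25"]], agg[["0"]])
})

test_that("more uniform evidence weighting reduces zero-cost sampling", {
  m <- beads_model("CostEvidence")
  base <- nt_point_params()
  trials <- generate_trials(make_design(16L, seed = 12), seed = 12)
  trials <- trials[trials$cost_level == "zero" &
                     trials$evidence_level == "high", ]
  sw <- sweep_parameter(m, base, "alpha_decay", c(0.3, 0.95), trials,
                        n_reps = 40, seed = 13)
  expect_lt(sw$mean_samples[sw$value == 0.95],
            sw$mean_samples[sw$value == 0.3])
})
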