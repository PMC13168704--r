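test_that("model registry defines the six variants with coherent stages", {
  expect_length(beads_models(), 6)
  for (name in beads_models()) {
    m <- beads_model(name)
    if (m$stages == 1L) {
      expect_length(m$stage2, 0)
      expect_identical(m$sec_cond, "none")
    } else {
      # cost and evidence DV roles are disjoint apart from the intercepts
      expect_length(intersect(setdiff(m$stage1, "intercept"),
                              setdiff(m$stage2, "intercept")), 0)
      expect_true(m$sec_cond %in% c("cost", "evidence"))
    }
    expect_setequal(names(m$par_transforms), m$par_names)
  }
  expect_error(beads_model("Nonsense"))
})

test_that("decayed cumulative information follows the leaky recursion", {
  expect_equal(decayed_ci(c("dog", "dog", "cat"), 1), 1)
  expect_equal(decayed_ci(c("dog", "cat", "cat"), 0), -1)
  expect_equal(decayed_ci(c("dog", "dog"), 0.5), 1.5)
  expect_equal(decayed_ci("DDC", 1), 1)            # compact string form
  expect_equal(decayed_ci(c(1, 1, -1), 1), 1)      # signed form
  expect_error(decayed_ci("DD", 1.5), "alpha")
  # boundary behaviours of the decay
  s <- c("dog", "cat", "cat", "dog", "dog")
  expect_equal(decayed_ci(s, 1), sum(stimuli_signs <- c(1, -1, -1, 1, 1)))
  expect_equal(decayed_ci(s, 0), 1)  # only the most recent sample survives
})

test_that("decision variables are assembled per decision point", {
  dvs <- build_dvs("DDCCD", c = 4, q = 0.8, alpha = 1)
  expect_equal(nrow(dvs), 6)  # j = 0..5
  expect_equal(dvs$draws, 0:5)
  expect_equal(dvs$cumu_cost, 4 * (0:5))
  expect_equal(dvs[dvs$j == 0, c("abs_cumu_info", "total_log_evid")],
               data.frame(abs_cumu_info = 0, total_log_evid = 0),
               ignore_attr = TRUE)
  expect_equal(dvs$cumu_cost[dvs$j == 3], 12)
  expect_equal(dvs$unit_evid, rep(log(4), 6))
  dv2 <- build_dvs(c("dog", "dog"), c = 0, q = 0.8, alpha = 1)
  expect_equal(dv2$total_log_evid[3], 2 * log(4))
})

test_that("stopping probabilities follow the one- and two-stage forms", {
  m1 <- beads_model("CostOnly")
  p0 <- stats::setNames(rep(0, 5), m1$par_names)
  dvs <- build_dvs(strrep("D", 20), c = 0, q = 0.6, alpha = 1, n_points = 3)
  expect_equal(stop_prob(m1, p0, dvs), rep(0.5, 4))
  # logistic identity through the intercept
  p1 <- p0; p1["beta_0"] <- log(3)
  expect_equal(stop_prob(m1, p1, dvs), rep(0.75, 4))
  # two-stage composition p1 + (1 - p1) p_sec p2
  m2 <- beads_model("Cost_Ccond_Evidence")
  pars <- stats::setNames(rep(0, length(m2$par_names)), m2$par_names)
  pars["s1_beta_0"] <- stats::qlogis(0.2)
  pars["s2_beta_0"] <- stats::qlogis(0.4)
  pars[c("p_sec_zero", "p_sec_low", "p_sec_high")] <- 0.5
  dvs0 <- build_dvs(strrep("D", 20), c = 0, q = 0.6, alpha = 0, n_points = 0)
  expect_equal(stop_prob(m2, pars, dvs0), 0.2 + 0.8 * 0.5 * 0.4)
  pars[c("p_sec_zero", "p_sec_low", "p_sec_high")] <- 0
  expect_equal(stop_prob(m2, pars, dvs0), 0.2)
  # p_sec = 1 with identical stage DVs gives independent hazards
  pars[c("p_sec_zero", "p_sec_low", "p_sec_high")] <- 1
  p1v <- stats::plogis(pars[["s1_beta_0"]])
  p2v <- stats::plogis(pars[["s2_beta_0"]])
  expect_equal(stop_prob(m2, pars, dvs0), 1 - (1 - p1v) * (1 - p2v))
  # second-thought probability selected by the trial's condition
  pars[c("p_sec_zero", "p_sec_low", "p_sec_high")] <- c(0, 0.5, 1)
  dvs_high <- build_dvs(strrep("D", 20), c = 4, q = 0.6, alpha = 0, n_points = 0)
  expect_gt(stop_prob(m2, pars, dvs_high), stop_prob(m2, pars, dvs0))
  expect_error(stop_prob(m2, p0, dvs0), "missing")
})

test_that("trial log-likelihood uses hazard semantics with forced stop at 20", {
  m <- beads_model("CostOnly")
  pars <- stats::setNames(rep(0, 5), m$par_names)  # constant p = 0.5
  tr <- fixed_trial(n_samples = 2, cost_level = "zero")
  expect_equal(trial_loglik(m, pars, tr), log(0.125))
  tr0 <- fixed_trial(n_samples = 0, cost_level = "zero")
  pars9 <- pars; pars9["beta_0"] <- stats::qlogis(0.9)
  expect_equal(trial_loglik(m, pars9, tr0), log(0.9))
  # certain continuation: forced stop contributes nothing
  parsm <- pars; parsm["beta_0"] <- -60
  tr20 <- fixed_trial(n_samples = 20, cost_level = "zero")
  expect_equal(trial_loglik(m, parsm, tr20), 0, tolerance = 1e-12)
  expect_error(trial_loglik(m, pars, fixed_trial(n_samples = 21)), "0..20")
})

test_that("trial log-likelihood drops when the stop hazard is pushed off the data", {
  m <- beads_model("CostEvidence")
  pars <- nt_point_params()
  tr <- fixed_trial(n_samples = 5)
  base <- trial_loglik(m, pars, tr)
  up <- pars; up["beta_0"] <- up["beta_0"] - 1   # less likely to stop at 5
  expect_lt(trial_loglik(m, up, tr), base + 1)   # continuity sanity
  # finite-difference: moving beta_0 to make p_5 tiny lowers the loglik
  down <- pars; down["beta_0"] <- down["beta_0"] - 30
  expect_lt(trial_loglik(m, down, tr), base)
})

test_that("stopping distributions normalise for all six models", {
  withr::local_seed(42)
  cond_grid <- beads_conditions()
  for (name in beads_models()) {
    m <- beads_model(name)
    for (r in 1:40) {
      pars <- random_params(m)
      i <- sample(nrow(cond_grid), 1)
      cond <- list(c = cond_grid$c[i], q = cond_grid$q[i])
      stim <- paste(sample(c("D", "C"), 20, replace = TRUE), collapse = "")
      d <- stopping_distribution(m, pars, stim, cond)
      expect_length(d, 21)
      expect_true(all(d >= 0))
      expect_equal(sum(d), 1, tolerance = 1e-12)
    }
  }
  # degenerate hazards
  m <- beads_model("CostOnly")
  p_hi <- stats::setNames(c(60, 0, 0, 0, 0), m$par_names)
  d_hi <- stopping_distribution(m, p_hi, strrep("D", 20),
                                beads_condition("zero", "low"))
  expect_equal(d_hi[1], 1, tolerance = 1e-12)
  p_lo <- stats::setNames(c(-60, 0, 0, 0, 0), m$par_names)
  d_lo <- stopping_distribution(m, p_lo, strrep("D", 20),
                                beads_condition("zero", "low"))
  expect_equal(d_lo[21], 1, tolerance = 1e-12)
})

test_that("dataset log-likelihood sums trials and carries trial history", {
  m <- beads_model("CostEvidence")
  pars <- nt_point_params()
  empty <- tiny_trial_table(integer(0))
  expect_equal(dataset_loglik(m, pars, empty)$total, 0)
  one <- tiny_trial_table(5L)
  expect_equal(dataset_loglik(m, pars, one)$total,
               trial_loglik(m, pars, fixed_trial(strrep("D", 20), "high",
                                                 "low", 5L)))
  # previous-trial decision variables must flow into the next trial
  two <- tiny_trial_table(c(5L, 7L))
  ll2 <- dataset_loglik(m, pars, two)
  second <- trial_loglik(m, pars,
                         fixed_trial(strrep("D", 20), "high", "low", 7L),
                         prev = list(last_draw = 5, last_correct = 1))
  expect_equal(ll2$pointwise[2], second)
  expect_gt(abs(second - ll2$pointwise[1]), 1e-8)  # history changes the value
  # unordered trials are rejected
  bad <- two[2:1, ]
  expect_error(dataset_loglik(m, pars, bad), "order")
})

test_that("the generating parameters dominate perturbed ones in likelihood", {
  withr::local_seed(7)
  m <- beads_model("CostEvidence")
  wins <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    gl <- default_group_params("NT")
    coh <- make_cohort(m, gl, 3, seed = 1000 + r, trials_per_miniblock = 4)
    truth <- lapply(seq_len(3), function(i) coh$params[i, ])
    names(truth) <- unique(coh$trials$participant_id)
    perturbed <- lapply(truth, function(p) {
      p["beta_draw"] <- p["beta_draw"] + sample(c(-2, 2), 1)
      p
    })
    ll_true <- dataset_loglik(m, truth, coh$trials)$total
    ll_pert <- dataset_loglik(m, perturbed, coh$trials)$total
    wins <- wins + (ll_true > ll_pert)
  }
  expect_gte(wins, ceiling(0.95 * n_rep))
})
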