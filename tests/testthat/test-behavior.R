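test_that("child summaries compute the five outcomes from hand-built trials", {
  # 4 trials at q = 0.6, c = 4 where the optimum is 1 sample
  tab <- tiny_trial_table(c(1L, 3L, 5L, 7L))
  s <- summarize_children(tab)
  expect_identical(nrow(s), 1L)
  expect_equal(s$mean_signed_deviation, 3)
  expect_equal(s$mean_samples, 4)
  expect_equal(s$accuracy, 1)
  expect_equal(s$sampling_variation, sd(c(1, 3, 5, 7)))
  expect_equal(s$mean_efficiency,
               mean(efficiency(c(1L, 3L, 5L, 7L), 0.6, 4)))
  # constant sampling has zero variation; all-correct zero-cost pays 100
  const <- tiny_trial_table(c(2L, 2L, 2L), cost_level = "zero")
  s2 <- summarize_children(const)
  expect_equal(s2$sampling_variation, 0)
  expect_equal(s2$mean_credits, 100)
  # single-trial condition: variation undefined, flagged as NA
  s3 <- summarize_children(tiny_trial_table(5L))
  expect_true(is.na(s3$sampling_variation))
  bad <- tiny_trial_table(1L)
  bad$cost_level <- "extreme"
  expect_error(summarize_children(bad), "labels")
})

test_that("summaries compose with forced-stopping simulation", {
  m <- beads_model("CostOnly")
  stopper <- stats::setNames(c(60, 0, 0, 0, 0), m$par_names)
  trials <- generate_trials(make_design(8L, seed = 41), seed = 41)
  sim <- simulate_agent(m, stopper, trials, seed = 42)
  sim$participant_id <- "S001"; sim$group <- "sim"
  s <- summarize_children(sim)
  expect_true(all(s$mean_samples == 0))
  # with zero samples every trial has the guessers' efficiency
  for (i in seq_len(nrow(s))) {
    cond <- beads_condition(s$cost_level[i], s$evidence_level[i])
    expect_equal(s$mean_efficiency[i], efficiency(0L, cond$q, cond$c))
  }
  expect_lt(abs(mean(s$accuracy) - 0.5), 0.2)
})

test_that("group contrasts return EMMs and adjusted group effects", {
  nt <- make_cohort("CostEvidence", default_group_params("NT"), 12, seed = 43,
                    group_label = "NT", id_prefix = "NT")
  asd <- make_cohort("CostEvidence", default_group_params("ASD"), 12,
                     seed = 44, group_label = "ASD", id_prefix = "ASD")
  s <- summarize_children(rbind(nt$trials, asd$trials))
  res <- fit_group_contrasts(s, "mean_samples")
  expect_s3_class(res$emmeans, "data.frame")
  expect_identical(nrow(res$emmeans), 12L)  # 2 groups x 6 conditions
  expect_true(all(c("overall", "by_cost") %in% names(res$group_contrasts)))
  expect_identical(nrow(res$group_contrasts$by_cost), 3L)
  # the generating difference is visible: ASD-like children sample more
  em <- res$emmeans
  expect_gt(mean(em$emmean[em$group == "ASD"]),
            mean(em$emmean[em$group == "NT"]))
  # sampling variation: ASD-like exceeds NT-like in costly conditions
  res_var <- fit_group_contrasts(s, "sampling_variation")
  emv <- res_var$emmeans
  costly <- emv$cost_level != "zero"
  expect_gt(mean(emv$emmean[costly & emv$group == "ASD"]),
            mean(emv$emmean[costly & emv$group == "NT"]))
  expect_error(fit_group_contrasts(s, "no_such_outcome"), "outcome")
})

test_that("contrasts on exchangeable groups stay near the nominal level", {
  withr::local_seed(45)
  pvals <- vapply(1:6, function(r) {
    a <- make_cohort("CostEvidence", default_group_params("NT"), 8,
                     seed = 500 + r, group_label = "A", id_prefix = "A")
    b <- make_cohort("CostEvidence", default_group_params("NT"), 8,
                     seed = 600 + r, group_label = "B", id_prefix = "B")
    s <- summarize_children(rbind(a$trials, b$trials))
    res <- fit_group_contrasts(s, "mean_efficiency")
    res$group_contrasts$overall$p.value[1]
  }, numeric(1))
  expect_gte(sum(pvals > 0.05), 5)
})

test_that("degenerate outcome columns give zero estimates", {
  a <- make_cohort("CostOnly", default_group_params("NT"), 4, seed = 46,
                   trials_per_miniblock = 2, group_label = "A", id_prefix = "A")
  b <- make_cohort("CostOnly", default_group_params("NT"), 4, seed = 47,
                   trials_per_miniblock = 2, group_label = "B", id_prefix = "B")
  s <- summarize_children(rbind(a$trials, b$trials))
  s$flat <- 0
  res <- suppressMessages(suppressWarnings(fit_group_contrasts(s, "flat")))
  expect_true(all(abs(res$emmeans$emmean) < 1e-10))
  expect_true(all(abs(res$group_contrasts$overall$estimate) < 1e-10))
})

test_that("parameter-behaviour correlations are ranked and FDR-adjusted", {
  ids <- sprintf("S%03d", 1:20)
  params <- data.frame(participant_id = ids, beta_last_draw = seq(-1, 1,
                                                                  length.out = 20))
  tabs <- do.call(rbind, lapply(seq_along(ids), function(i) {
    t <- tiny_trial_table(rep(3L, 3), id = ids[i])
    t$trial_index <- 1:3
    t
  }))
  s <- summarize_children(tabs)
  # build a perfectly monotone and a perfectly anti-monotone metric
  s$mono <- as.numeric(factor(s$participant_id, levels = ids))
  s$anti <- -s$mono
  pairs <- data.frame(parameter = "beta_last_draw", metric = c("mono", "anti"))
  res <- correlate_params_behavior(params, s, pairs)
  expect_equal(res$rho, c(1, -1))
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_error(
    correlate_params_behavior(params[1:3, ], s[s$participant_id %in% ids[1:3], ],
                              pairs[1, , drop = FALSE]),
    "4 complete pairs")
})

test_that("false discoveries stay near the nominal FDR under the null", {
  withr::local_seed(48)
  n_tests <- 20
  n_children <- 24
  fdp <- vapply(1:200, function(r) {
    x <- rnorm(n_children)
    p <- vapply(seq_len(n_tests), function(k) {
      suppressWarnings(cor.test(x, rnorm(n_children),
                                method = "spearman")$p.value)
    }, numeric(1))
    mean(p.adjust(p, "BH") < 0.05)
  }, numeric(1))
  expect_lte(mean(fdp), 0.05 + 0.01)
})
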