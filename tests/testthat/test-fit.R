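test_that("split R-hat separates mixed from disjoint chains", {
  withr::local_seed(1)
  good <- cbind(rnorm(1000), rnorm(1000))
  expect_lt(split_rhat(good), 1.01)
  bad <- cbind(rnorm(1000, 0), rnorm(1000, 10))
  expect_gt(split_rhat(bad), 1.01)
  # hand-computed split R-hat on a tiny fixture
  x <- matrix(c(1, 2, 3, 4), ncol = 1)  # splits: (1,2) and (3,4)
  W <- mean(c(var(c(1, 2)), var(c(3, 4))))
  B <- 2 * var(c(mean(c(1, 2)), mean(c(3, 4))))
  expect_equal(split_rhat(x), sqrt(((2 - 1) / 2 * W + B / 2) / W))
})

test_that("highest density intervals are shortest intervals", {
  expect_equal(hdi(rep(3, 50)), c(3, 3))
  withr::local_seed(2)
  draws <- rnorm(10000)
  h <- hdi(draws, 0.95)
  expect_lt(abs(h[1] + 1.96), 0.1)
  expect_lt(abs(h[2] - 1.96), 0.1)
  # strongly skewed draws: HDI hugs the mode, unlike the central interval
  sk <- rexp(10000)
  hs <- hdi(sk, 0.9)
  expect_lt(hs[1], stats::quantile(sk, 0.05))
})

test_that("presets record the retained-draw bookkeeping", {
  full <- mcmc_preset("full")
  expect_identical(full$chains * full$iter, 40000L)
  expect_identical(full$warmup, 5000L)
  desk <- mcmc_preset("desk")
  expect_true(desk$chains * desk$iter < full$chains * full$iter)
})

test_that("priors map every parameter with the right transform", {
  for (name in beads_models()) {
    m <- beads_model(name)
    pr <- default_priors(m)
    expect_setequal(names(pr$mu_loc), m$par_names)
    expect_identical(sum(pr$is_logit),
                     sum(m$par_transforms == "logit"))
    expect_true(all(pr$mu_scale > 0) && all(pr$sd_scale > 0))
  }
})

test_that("prior-predictive stopping behaviour spans the whole range", {
  # priors must not force degenerate stopping: across prior draws the
  # implied stopping times should reach both ends of 0..20
  withr::local_seed(3)
  m <- beads_model("CostEvidence")
  pr <- default_priors(m)
  cond <- beads_condition("low", "high")
  stim <- gen_stimuli(0.8, "dog")
  mins <- integer(0); maxs <- integer(0)
  for (r in 1:50) {
    mu <- rnorm(length(pr$mu_loc), pr$mu_loc, pr$mu_scale)
    names(mu) <- names(pr$mu_loc)
    pars <- transform_params(m, mu)
    d <- stopping_distribution(m, pars, stim, cond)
    mins <- c(mins, which(d > 1e-3)[1] - 1L)
    maxs <- c(maxs, max(which(d > 1e-3)) - 1L)
  }
  expect_lte(min(mins), 0)
  expect_gte(max(maxs), 20)
})

test_that("a small hierarchical fit is well-formed and reproducible", {
  coh <- make_cohort("CostOnly", default_group_params("NT"), 4, seed = 51,
                     trials_per_miniblock = 4)
  mc <- list(chains = 2L, warmup = 150L, iter = 150L)
  fit <- fit_hierarchical("CostOnly", coh$trials, mcmc = mc, seed = 9)
  P <- length(fit$model$par_names)
  expect_identical(dim(fit$draws$group_mean), c(150L, 2L, P))
  expect_identical(dim(fit$draws$child), c(150L, 2L, 4L * P))
  expect_identical(n_retained_draws(fit), 300L)
  # constrained child-level parameters respect their ranges
  expect_true(all(fit$draws$group_sd >= 0))
  # reproducibility under the same seed
  fit2 <- fit_hierarchical("CostOnly", coh$trials, mcmc = mc, seed = 9)
  expect_identical(fit$draws$group_mean, fit2$draws$group_mean)
  # diagnostics cover group means and SDs for every parameter
  expect_identical(nrow(fit$diagnostics$table), 2L * P + 1L)
  expect_error(fit_hierarchical("CostOnly", coh$trials[coh$trials$participant_id ==
                                  "S001", ], mcmc = mc), "2 children")
})

test_that("alpha_decay child draws live in (0, 1)", {
  coh <- make_cohort("CostEvidence", default_group_params("ASD"), 3, seed = 52,
                     trials_per_miniblock = 2)
  fit <- fit_hierarchical("CostEvidence", coh$trials,
                          mcmc = list(chains = 1L, warmup = 100L, iter = 100L),
                          seed = 2)
  cols <- grep("^alpha_decay", dimnames(fit$draws$child)[[3]])
  a <- fit$draws$child[, , cols]
  expect_true(all(a > 0 & a < 1))
})

test_that("group SDs shrink towards zero for a homogeneous cohort", {
  gl <- default_group_params("NT")
  gl$sd[] <- 0
  coh <- make_cohort("CostOnly", gl, 12, seed = 53)
  fit <- fit_hierarchical("CostOnly", coh$trials,
                          mcmc = list(chains = 2L, warmup = 600L, iter = 600L),
                          seed = 3)
  prior_median <- stats::qnorm(0.75)  # median of half-normal(1)
  sd_draws <- as.vector(fit$draws$group_sd[, , "beta_0"])
  expect_lt(stats::median(sd_draws), prior_median)
})

test_that("group summaries report medians and HDIs on both scales", {
  coh <- make_cohort("CostEvidence", default_group_params("NT"), 3, seed = 54,
                     trials_per_miniblock = 2)
  fit <- fit_hierarchical("CostEvidence", coh$trials,
                          mcmc = list(chains = 1L, warmup = 100L, iter = 100L),
                          seed = 4)
  s <- extract_group_summary(fit, "alpha_decay", scale = "natural")
  expect_true(s$median > 0 && s$median < 1)
  expect_true(s$hdi[1] <= s$median && s$median <= s$hdi[2])
  su <- extract_group_summary(fit, "alpha_decay", what = "sd")
  expect_gte(su$hdi[1], 0)
  expect_error(extract_group_summary(fit, "beta_nope"), "unknown parameter")
})
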