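# Simulation-based calibration: prior draws -> simulated datasets -> refit
# -> rank statistics -> uniformity assessment.

#' SBC settings used for a paper-scale run
#'
#' @return List with `N` (1000 replicates), `D` (400 retained draws per fit),
#'   `chains` (2), `thin` (10), `warmup` (1000): thinning 2 chains x 2000
#'   post-warmup draws by 10 yields the 400 rank bins.
#' @export
sbc_full_settings <- function() {
  list(N = 1000L, D = 400L, chains = 2L, thin = 10L, warmup = 1000L)
}

sbc_result <- function(ranks, truths, post_means, D, failures) {
  structure(
    list(ranks = ranks, truths = truths, post_means = post_means, D = D,
         N = nrow(ranks), failures = failures),
    class = "beads_sbc"
  )
}

#' SBC on an analytically tractable toy model
#'
#' Conjugate check of the rank machinery: a normal mean with known
#' observation variance, `mu ~ N(prior_mean, prior_sd)`, data
#' `y_1..y_nobs ~ N(mu, sigma_obs)`. The posterior is available in closed
#' form, so the ranks isolate the calibration of the SBC procedure itself.
#' `posterior_sd_inflation != 1` deliberately mis-scales the posterior (a
#' broken-inference detector check).
#'
#' @param N Number of SBC replicates.
#' @param D Posterior draws per replicate (ranks lie in 0..D).
#' @param n_obs Observations per simulated dataset.
#' @param prior_mean,prior_sd Prior on the mean.
#' @param sigma_obs Known observation SD.
#' @param posterior_sd_inflation Multiplier applied to the posterior SD
#'   (1 = correct inference).
#' @param seed Integer seed.
#' @return A `beads_sbc` object with a single parameter `mu`.
#' @export
run_sbc_toy <- function(N = 200L, D = 400L, n_obs = 10L, prior_mean = 0,
                        prior_sd = 1, sigma_obs = 1,
                        posterior_sd_inflation = 1, seed = NULL) {
  with_seed(seed, {
    ranks <- matrix(NA_integer_, N, 1, dimnames = list(NULL, "mu"))
    truths <- matrix(NA_real_, N, 1, dimnames = list(NULL, "mu"))
    post_means <- truths
    for (r in seq_len(N)) {
      mu_true <- stats::rnorm(1, prior_mean, prior_sd)
      y <- stats::rnorm(n_obs, mu_true, sigma_obs)
      prec <- 1 / prior_sd^2 + n_obs / sigma_obs^2
      post_mu <- (prior_mean / prior_sd^2 + sum(y) / sigma_obs^2) / prec
      post_sd <- sqrt(1 / prec) * posterior_sd_inflation
      draws <- stats::rnorm(D, post_mu, post_sd)
      ranks[r, 1] <- sum(draws < mu_true)
      truths[r, 1] <- mu_true
      post_means[r, 1] <- post_mu
    }
    sbc_result(ranks, truths, post_means, D, failures = 0L)
  })
}

#' Simulation-based calibration of the hierarchical fitting pipeline
#'
#' For each replicate: draw group-level means and SDs from the modelling
#' priors, simulate a cohort with [make_cohort()], refit with
#' [fit_hierarchical()], thin the retained draws to `D`, and record the rank
#' of each true group-level mean within its posterior draws. Replicate-level
#' fit failures are recorded and excluded, never silently dropped.
#'
#' @inheritParams stop_prob
#' @param N Number of SBC replicates.
#' @param D Retained draws per fit after thinning.
#' @param n_children Children per simulated cohort.
#' @param trials_per_miniblock Trials per condition cell.
#' @param mcmc MCMC settings for the refits (`chains * iter` must be at
#'   least `D`).
#' @param priors Prior specification (defaults to [default_priors()]).
#' @param seed Integer seed.
#' @return A `beads_sbc` with one column per group-level mean parameter.
#' @export
run_sbc <- function(model, N = 50L, D = 100L, n_children = 8L,
                    trials_per_miniblock = 8L, mcmc = NULL, priors = NULL,
                    seed = NULL) {
  if (!inherits(model, "beads_model")) model <- beads_model(model)
  if (is.null(priors)) priors <- default_priors(model)
  if (is.null(mcmc)) mcmc <- list(chains = 2L, warmup = 400L, iter = 400L)
  total_draws <- mcmc$chains * mcmc$iter
  if (total_draws < D) stop("mcmc settings yield fewer than D draws", call. = FALSE)
  pn <- model$par_names
  P <- length(pn)
  with_seed(seed, {
    ranks <- matrix(NA_integer_, N, P, dimnames = list(NULL, pn))
    truths <- matrix(NA_real_, N, P, dimnames = list(NULL, pn))
    post_means <- truths
    failures <- 0L
    for (r in seq_len(N)) {
      mu_true <- stats::rnorm(P, priors$mu_loc, priors$mu_scale)
      sd_true <- abs(stats::rnorm(P, 0, priors$sd_scale))
      names(mu_true) <- names(sd_true) <- pn
      rep_seed <- sample.int(2^30, 1)
      res <- tryCatch({
        cohort <- make_cohort(model, list(mean = mu_true, sd = sd_true),
                              n_children, seed = rep_seed,
                              trials_per_miniblock = trials_per_miniblock)
        fit <- fit_hierarchical(model, cohort$trials, priors = priors,
                                mcmc = mcmc, seed = rep_seed + 1L)
        keep <- round(seq(1, total_draws, length.out = D))
        mu_draws <- apply(fit$draws$group_mean, 3, identity)  # draws x P
        mu_draws <- mu_draws[keep, , drop = FALSE]
        list(ranks = colSums(mu_draws < rep(mu_true, each = D)),
             means = colMeans(mu_draws))
      }, error = function(e) NULL)
      if (is.null(res)) {
        failures <- failures + 1L
        next
      }
      ranks[r, ] <- res$ranks
      truths[r, ] <- mu_true
      post_means[r, ] <- res$means
    }
    keep_rows <- !is.na(ranks[, 1])
    sbc_result(ranks[keep_rows, , drop = FALSE],
               truths[keep_rows, , drop = FALSE],
               post_means[keep_rows, , drop = FALSE], D, failures)
  })
}

#' Uniformity check of SBC rank statistics
#'
#' Chi-square goodness-of-fit over binned ranks, plus an approximate
#' simultaneous ECDF band (pointwise binomial bands at a Sidak-adjusted
#' level).
#'
#' @param ranks Integer ranks in 0..D.
#' @param D Posterior draws per replicate.
#' @param bins Number of rank bins (default 20).
#' @param alpha Test level.
#' @return List with `statistic`, `df`, `p_value`, `pass` (chi-square
#'   decision), `ecdf_ok` (band diagnostic) and `warning` for small N.
#' @export
uniformity_check <- function(ranks, D, bins = 20L, alpha = 0.05) {
  ranks <- ranks[!is.na(ranks)]
  n <- length(ranks)
  if (any(ranks < 0 | ranks > D)) stop("ranks outside 0..D", call. = FALSE)
  small <- n < 20
  if (small) warning("fewer than 20 ranks: uniformity bands are wide")
  # bin ranks 0..D into `bins` near-equal cells
  cell <- pmin(bins - 1L, floor(ranks * bins / (D + 1))) + 1L
  obs <- tabulate(cell, nbins = bins)
  expected <- n / bins
  statistic <- sum((obs - expected)^2 / expected)
  df <- bins - 1L
  p_value <- stats::pchisq(statistic, df, lower.tail = FALSE)
  # ECDF band: pointwise binomial at Sidak-adjusted level over bins points
  u <- sort(ranks) / D
  grid <- seq(0.05, 0.95, length.out = 19)
  gamma <- 1 - (1 - alpha)^(1 / length(grid))
  ecdf_vals <- vapply(grid, function(g) mean(u <= g), numeric(1))
  lo <- stats::qbinom(gamma / 2, n, grid) / n
  hi <- stats::qbinom(1 - gamma / 2, n, grid) / n
  ecdf_ok <- all(ecdf_vals >= lo & ecdf_vals <= hi)
  list(statistic = statistic, df = df, p_value = p_value,
       pass = p_value > alpha, ecdf_ok = ecdf_ok, n = n, warning = small)
}

#' Parameter-recovery summary of an SBC run
#'
#' @param sbc A `beads_sbc` object.
#' @param flag_below Correlation threshold below which a parameter is
#'   flagged as weakly recovered.
#' @return Data frame: `parameter`, `correlation` (Spearman, true vs
#'   posterior mean), `flagged`.
#' @export
recovery_summary <- function(sbc, flag_below = 0.5) {
  if (nrow(sbc$truths) < 3) stop("need at least 3 replicates", call. = FALSE)
  pn <- colnames(sbc$truths)
  cors <- vapply(pn, function(p) {
    suppressWarnings(stats::cor(sbc$truths[, p], sbc$post_means[, p],
                                method = "spearman"))
  }, numeric(1))
  data.frame(parameter = pn, correlation = unname(cors),
             flagged = unname(!is.finite(cors) | cors < flag_below))
}
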