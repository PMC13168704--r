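# Model comparison: PSIS-LOO ELPD, Pseudo-BMA+ weights, posterior
# predictive checks.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Generalized Pareto fit to exceedances (Zhang & Stephens 2009 profile
# estimator with their weak prior); returns shape k and scale sigma.
gpd_fit <- function(y) {
  y <- sort(y)
  n <- length(y)
  if (n < 5 || y[n] <= 0) return(list(k = NaN, sigma = NaN))
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  ystar <- y[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / y[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * ystar)
  kk <- vapply(theta, function(t) mean(log1p(-t * y)), numeric(1))
  l_theta <- n * (log(-theta / kk) - kk - 1)
  w <- exp(l_theta - logsumexp(l_theta))
  theta_hat <- sum(w * theta)
  k <- mean(log1p(-theta_hat * y))
  sigma <- -k / theta_hat
  # weakly informative prior pulling k towards 0.5 (stabilises small tails)
  k <- (n * k + 10 * 0.5) / (n + 10)
  list(k = k, sigma = sigma)
}

# Pareto-smooth one vector of log importance ratios (log weights).
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- min(ceiling(0.2 * S), ceiling(3 * sqrt(S)))
  if (M < 5) return(list(lw = lw, k = NaN))
  ord <- order(lw)
  tail_idx <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exceed <- exp(lw[tail_idx]) - exp(cutoff)
  if (stats::sd(exceed) == 0) return(list(lw = lw, k = Inf))
  fit <- gpd_fit(exceed)
  if (!is.finite(fit$k)) return(list(lw = lw, k = fit$k))
  # replace the tail by expected order statistics of the fitted GPD
  p <- (seq_len(M) - 0.5) / M
  q <- if (abs(fit$k) < 1e-12) {
    -fit$sigma * log1p(-p)
  } else {
    fit$sigma / fit$k * ((1 - p)^(-fit$k) - 1)
  }
  smoothed <- log(exp(cutoff) + q)
  smoothed <- pmin(smoothed, 0)  # truncate at the raw maximum
  lw[tail_idx] <- smoothed
  list(lw = lw, k = fit$k)
}

#' PSIS-LOO expected log predictive density
#'
#' Leave-one-out cross-validation estimate of the expected log predictive
#' density from a matrix of pointwise log-likelihoods, using Pareto-smoothed
#' importance sampling: per observation, importance ratios 1/p(y_i | theta_s)
#' are tail-smoothed by a generalized Pareto fit and the LOO predictive
#' density is their weighted average. Pareto shape diagnostics above
#' `k_threshold` flag observations with unreliable importance weights.
#'
#' @param loglik Matrix of pointwise log-likelihoods, draws x observations.
#' @param k_threshold Pareto-k flag threshold (default 0.7).
#' @return List with `elpd_loo`, `se_elpd`, `pointwise` (per-observation
#'   elpd), `pareto_k` and `n_bad_k`.
#' @export
psis_loo <- function(loglik, k_threshold = 0.7) {
  loglik <- as.matrix(loglik)
  if (nrow(loglik) < 2) stop("need at least 2 draws", call. = FALSE)
  if (any(!is.finite(loglik))) {
    stop("non-finite pointwise log-likelihoods", call. = FALSE)
  }
  n <- ncol(loglik)
  pointwise <- numeric(n)
  pareto_k <- numeric(n)
  for (i in seq_len(n)) {
    ll <- loglik[, i]
    sm <- psis_smooth(-ll)
    pointwise[i] <- logsumexp(sm$lw + ll) - logsumexp(sm$lw)
    pareto_k[i] <- sm$k
  }
  list(
    elpd_loo = sum(pointwise),
    se_elpd = sqrt(n * stats::var(pointwise)),
    pointwise = pointwise,
    pareto_k = pareto_k,
    n_bad_k = sum(is.finite(pareto_k) & pareto_k > k_threshold |
                    is.infinite(pareto_k))
  )
}

#' Pseudo-BMA+ model weights
#'
#' Pseudo-Bayesian model averaging with Bayesian-bootstrap regularisation:
#' observation weights are drawn from a uniform Dirichlet, each bootstrap
#' replicate's weighted total elpd is passed through a softmax across
#' models, and the replicate weights are averaged.
#'
#' @param elpd_pointwise Matrix (observations x models) or list of aligned
#'   pointwise elpd vectors.
#' @param n_bootstrap Number of Bayesian-bootstrap replicates.
#' @param seed Optional integer seed.
#' @return Named weight vector summing to 1.
#' @export
pseudo_bma_plus <- function(elpd_pointwise, n_bootstrap = 1000L, seed = NULL) {
  if (is.list(elpd_pointwise) && !is.matrix(elpd_pointwise)) {
    lens <- lengths(elpd_pointwise)
    if (length(unique(lens)) != 1L) {
      stop("pointwise elpd vectors have different lengths", call. = FALSE)
    }
    elpd_pointwise <- do.call(cbind, elpd_pointwise)
  }
  elpd_pointwise <- as.matrix(elpd_pointwise)
  M <- ncol(elpd_pointwise)
  if (M < 2) stop("need at least 2 models", call. = FALSE)
  n <- nrow(elpd_pointwise)
  with_seed(seed, {
    w_acc <- numeric(M)
    for (b in seq_len(n_bootstrap)) {
      g <- stats::rexp(n)
      wb <- g / sum(g)
      z <- n * colSums(wb * elpd_pointwise)
      z <- z - max(z)
      w_acc <- w_acc + exp(z) / sum(exp(z))
    }
    w <- w_acc / n_bootstrap
    w <- w / sum(w)
    names(w) <- colnames(elpd_pointwise)
    w
  })
}

#' Pointwise log-likelihood draws from a hierarchical fit
#'
#' @param fit A `beads_fit`.
#' @param thin Keep every `thin`-th retained draw.
#' @return Matrix draws x trials (trials in the fit's data order).
#' @export
pointwise_loglik <- function(fit, thin = 1L) {
  iter <- dim(fit$draws$child)[1]
  chains <- dim(fit$draws$child)[2]
  keep <- seq(1L, iter, by = thin)
  theta <- do.call(rbind, lapply(seq_len(chains), function(k) {
    fit$draws$child[keep, k, , drop = TRUE]
  }))
  cpp_pointwise_ll_draws(model_code(fit$model), theta, fit$data_arrays)
}

#' Posterior predictive stopping distributions
#'
#' Averages the analytic stopping-time distribution of every trial (given
#' its full 20-symbol stimulus sequence) over posterior draws, and tabulates
#' the result against the observed sample-number histogram per group and
#' condition.
#'
#' @param fit A `beads_fit`.
#' @param thin Draw thinning for the predictive average (default keeps at
#'   most ~200 draws).
#' @return Data frame: `group`, `cost_level`, `evidence_level`, `n` (0..20),
#'   `predicted` (mean predictive probability) and `observed` (empirical
#'   proportion).
#' @export
posterior_predictive <- function(fit, thin = NULL) {
  iter <- dim(fit$draws$child)[1]
  chains <- dim(fit$draws$child)[2]
  if (is.null(thin)) thin <- max(1L, floor(iter * chains / 200))
  keep <- seq(1L, iter, by = thin)
  theta <- do.call(rbind, lapply(seq_len(chains), function(k) {
    fit$draws$child[keep, k, , drop = TRUE]
  }))
  pred <- cpp_predictive_dist(model_code(fit$model), theta, fit$data_arrays)
  trials <- fit$data
  key <- interaction(trials$group, trials$cost_level, trials$evidence_level,
                     drop = TRUE)
  out <- list()
  for (lev in levels(key)) {
    idx <- which(key == lev)
    parts <- strsplit(lev, ".", fixed = TRUE)[[1]]
    obs <- tabulate(trials$n_samples[idx] + 1L, nbins = 21L) / length(idx)
    out[[lev]] <- data.frame(
      group = parts[1], cost_level = parts[2], evidence_level = parts[3],
      n = 0:20, predicted = colMeans(pred[idx, , drop = FALSE]),
      observed = obs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare fitted models within one group
#'
#' @param fits Named list of `beads_fit` objects for the same dataset.
#' @param thin Draw thinning passed to [pointwise_loglik()].
#' @param n_bootstrap Bootstrap replicates for [pseudo_bma_plus()].
#' @param seed Optional integer seed for the bootstrap.
#' @return Data frame sorted by elpd: `model`, `elpd_loo`, `se_elpd`,
#'   `delta_elpd` (vs the best model), `se_delta`, `weight_pbma_plus`,
#'   `n_bad_k`.
#' @export
compare_models <- function(fits, thin = 1L, n_bootstrap = 1000L, seed = NULL) {
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) f$model$name, character(1))
  }
  if (length(fits) == 1L) {
    f <- fits[[1]]
    loo <- psis_loo(pointwise_loglik(f, thin))
    return(data.frame(model = names(fits), elpd_loo = loo$elpd_loo,
                      se_elpd = loo$se_elpd, delta_elpd = 0, se_delta = 0,
                      weight_pbma_plus = 1, n_bad_k = loo$n_bad_k))
  }
  ref <- fits[[1]]$data
  for (f in fits) {
    if (nrow(f$data) != nrow(ref) ||
        !identical(f$data$participant_id, ref$participant_id) ||
        !identical(f$data$n_samples, ref$n_samples)) {
      stop("fits were not computed on the same dataset", call. = FALSE)
    }
  }
  loos <- lapply(fits, function(f) psis_loo(pointwise_loglik(f, thin)))
  pw <- do.call(cbind, lapply(loos, `[[`, "pointwise"))
  colnames(pw) <- names(fits)
  weights <- pseudo_bma_plus(pw, n_bootstrap = n_bootstrap, seed = seed)
  elpd <- vapply(loos, `[[`, numeric(1), "elpd_loo")
  best <- which.max(elpd)
  delta <- elpd - elpd[best]
  se_delta <- vapply(seq_along(loos), function(m) {
    if (m == best) return(0)
    d <- pw[, m] - pw[, best]
    sqrt(length(d) * stats::var(d))
  }, numeric(1))
  out <- data.frame(
    model = names(fits), elpd_loo = elpd,
    se_elpd = vapply(loos, `[[`, numeric(1), "se_elpd"),
    delta_elpd = delta, se_delta = se_delta,
    weight_pbma_plus = unname(weights[names(fits)]),
    n_bad_k = vapply(loos, `[[`, numeric(1), "n_bad_k"))
  out <- out[order(-out$elpd_loo), ]
  rownames(out) <- NULL
  out
}
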