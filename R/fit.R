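# Hierarchical Bayesian estimation of the stopping models.
#
# Child-level parameters are normal on the unconstrained scale around
# group-level means, with a non-centered construction (standard-normal
# latents scaled by group SDs); alpha_decay and the second-thought
# probabilities are mapped to (0, 1) through the logistic function. Sampling
# uses a blockwise adaptive random-walk Metropolis sampler (implemented in
# C++) with Robbins-Monro scale adaptation during warm-up.

#' MCMC settings presets
#'
#' `"desk"` (2 chains, 2000 warm-up, 2000 sampling iterations) is sized for
#' interactive use and testing; `"full"` (4 chains, 5000 warm-up, 10,000
#' sampling iterations, hence 40,000 retained draws per parameter) matches
#' the scale used for the study-size analyses.
#'
#' @param preset `"desk"` or `"full"`.
#' @return List with `chains`, `warmup`, `iter`.
#' @export
mcmc_preset <- function(preset = c("desk", "full")) {
  preset <- match.arg(preset)
  switch(preset,
    desk = list(chains = 2L, warmup = 2000L, iter = 2000L),
    full = list(chains = 4L, warmup = 5000L, iter = 10000L)
  )
}

#' Default prior specification for a model
#'
#' Weakly informative defaults: group means ~ Normal(0, 2) on the
#' unconstrained scale (identity for logistic coefficients on raw decision
#' variables, log-odds for `alpha_decay` and the second-thought
#' probabilities), group SDs ~ half-Normal(1).
#'
#' @inheritParams stop_prob
#' @param mu_scale Scale of the normal prior on group means.
#' @param sd_scale Scale of the half-normal prior on group SDs.
#' @return A `PriorSpec` list with per-parameter vectors `mu_loc`,
#'   `mu_scale`, `sd_scale` and `is_logit`.
#' @export
default_priors <- function(model, mu_scale = 2, sd_scale = 1) {
  if (!inherits(model, "beads_model")) model <- beads_model(model)
  P <- length(model$par_names)
  list(
    par_names = model$par_names,
    mu_loc = stats::setNames(rep(0, P), model$par_names),
    mu_scale = stats::setNames(rep(mu_scale, P), model$par_names),
    sd_scale = stats::setNames(rep(sd_scale, P), model$par_names),
    is_logit = stats::setNames(
      as.integer(model$par_transforms == "logit"), model$par_names)
  )
}

model_code <- function(model) {
  match(model$name, beads_models())
}

# Flatten a trial table into the arrays consumed by the C++ likelihood.
prepare_fit_data <- function(trials) {
  trials <- ensure_cq(trials)
  trials <- trials[order(trials$participant_id, trials$trial_index), ]
  ids <- unique(trials$participant_id)
  child <- match(trials$participant_id, ids) - 1L
  n_tr <- nrow(trials)
  S <- matrix(0L, n_tr, 20)
  for (i in seq_len(n_tr)) S[i, ] <- stimuli_to_signed(trials$stimuli[i])
  prev_draw <- numeric(n_tr)
  prev_correct <- numeric(n_tr)
  for (id in seq_along(ids) - 1L) {
    idx <- which(child == id)
    if (length(idx) > 1L) {
      lead <- idx[-length(idx)]
      prev_draw[idx[-1L]] <- trials$n_samples[lead]
      prev_correct[idx[-1L]] <- ifelse(trials$correct[lead] == 1, 1, -1)
    }
  }
  starts <- vapply(seq_along(ids), function(i) min(which(child == i - 1L)),
                   integer(1))
  ends <- vapply(seq_along(ids), function(i) max(which(child == i - 1L)),
                 integer(1))
  list(
    arrays = list(
      child = child, n = as.integer(trials$n_samples),
      highev = as.integer(trials$q > 0.7),
      child_start = starts - 1L, child_end = ends - 1L,
      c = as.numeric(trials$c), L = log(trials$q / (1 - trials$q)),
      prev_draw = prev_draw, prev_correct = prev_correct, S = S
    ),
    ids = ids, trials = trials
  )
}

# Plausible per-parameter posterior scales used to seed proposal
# preconditioning before the running variance takes over.
init_proposal_scale <- function(model) {
  s <- rep(0.3, length(model$par_names))
  names(s) <- model$par_names
  s[grepl("beta_draw$", names(s))] <- 0.05
  s[grepl("beta_cumu_cost$", names(s))] <- 0.03
  s[grepl("beta_last_draw$", names(s))] <- 0.03
  s[grepl("beta_(abs_cumu_info|total_log_evid)$", names(s))] <- 0.08
  s
}

#' Fit a stopping model hierarchically to one group
#'
#' @inheritParams stop_prob
#' @param dataset Trial data frame in the canonical schema (one group; >= 2
#'   children, each with >= 1 trial).
#' @param priors A [default_priors()] specification.
#' @param mcmc An [mcmc_preset()] (or list with `chains`, `warmup`, `iter`).
#' @param seed Integer seed; chain `k` runs under `seed + k - 1`.
#' @return A `beads_fit` object: posterior draw arrays (`group_mean` and
#'   `group_sd` on the unconstrained scale, `child` on the natural scale,
#'   each `iterations x chains x parameters`), convergence diagnostics,
#'   acceptance rates, the prepared data, and all settings. Non-convergence
#'   (any split R-hat >= 1.01) is flagged in `$diagnostics$pass`, not hidden.
#' @export
fit_hierarchical <- function(model, dataset, priors = NULL,
                             mcmc = mcmc_preset("desk"), seed = 1L) {
  if (!inherits(model, "beads_model")) model <- beads_model(model)
  if (is.null(priors)) priors <- default_priors(model)
  prep <- prepare_fit_data(dataset)
  C <- length(prep$ids)
  if (C < 2L) stop("need at least 2 children", call. = FALSE)
  if (any(!vapply(mcmc[c("chains", "warmup", "iter")], function(x) x >= 1,
                  logical(1)))) {
    stop("mcmc settings must be positive", call. = FALSE)
  }
  P <- length(model$par_names)
  prior_list <- list(mu_loc = unname(priors$mu_loc),
                     mu_scale = unname(priors$mu_scale),
                     sd_scale = unname(priors$sd_scale),
                     is_logit = unname(priors$is_logit))
  chains <- vector("list", mcmc$chains)
  for (k in seq_len(mcmc$chains)) {
    chains[[k]] <- with_seed(seed + k - 1L, {
      cpp_fit_chain(model_code(model), prep$arrays, prior_list,
                    as.integer(mcmc$warmup), as.integer(mcmc$iter),
                    unname(init_proposal_scale(model)))
    })
  }
  iter <- mcmc$iter
  group_mean <- array(NA_real_, c(iter, mcmc$chains, P),
                      dimnames = list(NULL, NULL, model$par_names))
  group_sd <- group_mean
  child <- array(NA_real_, c(iter, mcmc$chains, C * P),
                 dimnames = list(NULL, NULL,
                                 paste0(rep(model$par_names, each = C), "[",
                                        rep(prep$ids, P), "]")))
  for (k in seq_len(mcmc$chains)) {
    group_mean[, k, ] <- chains[[k]]$mu
    group_sd[, k, ] <- chains[[k]]$sigma
    child[, k, ] <- chains[[k]]$theta
  }
  fit <- structure(
    list(model = model, draws = list(group_mean = group_mean,
                                     group_sd = group_sd, child = child),
         participant_ids = prep$ids, data = prep$trials,
         data_arrays = prep$arrays, priors = priors, mcmc = mcmc, seed = seed,
         accept = lapply(chains, `[[`, "accept")),
    class = "beads_fit"
  )
  fit$diagnostics <- diagnostics_report(fit)
  fit
}

#' @method print beads_fit
#' @export
print.beads_fit <- function(x, ...) {
  cat("Hierarchical fit of model", x$model$name, "\n")
  cat(sprintf("  %d children, %d trials; %d chains x %d draws (+%d warmup)\n",
              length(x$participant_ids), nrow(x$data), x$mcmc$chains,
              x$mcmc$iter, x$mcmc$warmup))
  cat(sprintf("  retained draws per parameter: %d\n",
              x$mcmc$chains * x$mcmc$iter))
  cat(sprintf("  convergence pass: %s (max split R-hat %.3f)\n",
              x$diagnostics$pass, max(x$diagnostics$table$rhat)))
  invisible(x)
}

#' Number of retained posterior draws per parameter
#' @param fit A `beads_fit`.
#' @return Integer count (chains x sampling iterations).
#' @export
n_retained_draws <- function(fit) {
  as.integer(fit$mcmc$chains * fit$mcmc$iter)
}

#' Split R-hat of a draws matrix
#'
#' Gelman-Rubin potential scale reduction computed after splitting each chain
#' in half.
#'
#' @param x Matrix of draws, iterations x chains.
#' @return Scalar R-hat.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  splits <- do.call(cbind, lapply(seq_len(ncol(x)), function(k) {
    cbind(x[seq_len(half), k], x[(n - half + 1):n, k])
  }))
  m <- ncol(splits)
  nn <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  B <- nn * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# Effective sample size via Geyer's initial monotone positive sequence,
# averaged across chains.
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  if (stats::sd(as.vector(x)) == 0) return(NA_real_)
  max_lag <- min(n - 1, 200)
  rho <- matrix(0, max_lag + 1, m)
  for (k in seq_len(m)) {
    ac <- stats::acf(x[, k], lag.max = max_lag, plot = FALSE,
                     demean = TRUE)$acf[, 1, 1]
    rho[, k] <- ac
  }
  r <- rowMeans(rho)  # r[1] is lag 0
  # Geyer initial positive sequence: add lag pairs while their sum is positive
  s <- 0
  t <- 2
  while (t + 1 <= length(r)) {
    pair <- r[t] + r[t + 1]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  ess <- m * n / (1 + 2 * s)
  max(1, min(ess, m * n))
}

#' Convergence diagnostics for a hierarchical fit
#'
#' @param fit A `beads_fit` object.
#' @return List with `table` (per-parameter split R-hat and ESS for group
#'   means and SDs, plus the worst child-level R-hat), `max_rhat`,
#'   `divergences` (always 0: the random-walk sampler has no divergent
#'   transitions) and `pass` (all R-hat < 1.01).
#' @export
diagnostics_report <- function(fit) {
  if (!inherits(fit, "beads_fit")) stop("not a beads_fit", call. = FALSE)
  pn <- fit$model$par_names
  rows <- list()
  for (p in seq_along(pn)) {
    for (what in c("group_mean", "group_sd")) {
      x <- fit$draws[[what]][, , p, drop = TRUE]
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = paste0(what, ".", pn[p]),
        rhat = split_rhat(x), ess = ess_basic(x))
    }
  }
  child_rhat <- apply(fit$draws$child, 3, split_rhat)
  worst <- which.max(child_rhat)
  rows[[length(rows) + 1L]] <- data.frame(
    parameter = paste0("child.", names(worst)),
    rhat = unname(child_rhat[worst]),
    ess = ess_basic(fit$draws$child[, , worst, drop = TRUE]))
  table <- do.call(rbind, rows)
  max_rhat <- max(c(table$rhat, child_rhat), na.rm = TRUE)
  list(table = table, max_rhat = max_rhat, divergences = 0L,
       pass = is.finite(max_rhat) && max_rhat < 1.01)
}

#' Highest density interval of a sample
#'
#' @param draws Numeric vector of posterior draws.
#' @param prob Mass of the interval (default 0.95).
#' @return Numeric vector `c(lower, upper)`: the shortest interval holding
#'   `prob` of the draws.
#' @export
hdi <- function(draws, prob = 0.95) {
  draws <- sort(draws[is.finite(draws)])
  n <- length(draws)
  if (n == 0L) stop("no finite draws", call. = FALSE)
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(draws[1], draws[n]))
  widths <- draws[(k + 1):n] - draws[seq_len(n - k)]
  i <- which.min(widths)
  c(draws[i], draws[i + k])
}

#' Posterior summary of a group-level parameter
#'
#' @param fit A `beads_fit`.
#' @param parameter Parameter name (see `fit$model$par_names`).
#' @param what `"mean"` (group-level mean) or `"sd"` (group-level SD).
#' @param scale `"unconstrained"` (the fitting scale) or `"natural"`
#'   (group-mean draws mapped through the parameter's transform; only for
#'   `what = "mean"`).
#' @param prob HDI mass.
#' @return List with `median` and `hdi`.
#' @export
extract_group_summary <- function(fit, parameter,
                                  what = c("mean", "sd"),
                                  scale = c("unconstrained", "natural"),
                                  prob = 0.95) {
  what <- match.arg(what)
  scale <- match.arg(scale)
  pn <- fit$model$par_names
  if (!parameter %in% pn) stop("unknown parameter: ", parameter, call. = FALSE)
  arr <- if (what == "mean") fit$draws$group_mean else fit$draws$group_sd
  draws <- as.vector(arr[, , match(parameter, pn)])
  if (scale == "natural" && what == "mean" &&
      fit$model$par_transforms[[parameter]] == "logit") {
    draws <- stats::plogis(draws)
  }
  list(median = stats::median(draws), hdi = hdi(draws, prob))
}

#' Posterior-mean child-level parameters
#'
#' @param fit A `beads_fit`.
#' @return Data frame: one row per child, one column per parameter (natural
#'   scale), plus `participant_id`.
#' @export
child_posterior_means <- function(fit) {
  C <- length(fit$participant_ids)
  P <- length(fit$model$par_names)
  flat <- apply(fit$draws$child, 3, mean)
  m <- matrix(flat, nrow = C, ncol = P,
              dimnames = list(NULL, fit$model$par_names))
  cbind(data.frame(participant_id = fit$participant_ids,
                   stringsAsFactors = FALSE), as.data.frame(m))
}
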