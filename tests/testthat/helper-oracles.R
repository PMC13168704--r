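# Independent oracles and small fixtures used across the suite.

# Exhaustive enumeration of all 2^n stimulus outcomes: probability that the
# majority of n draws matches the predominant side, ties split by a fair
# coin. Independent of the binomial-summation implementation.
enumerate_correct_prob <- function(n, q) {
  if (n == 0) return(0.5)
  p <- 0
  for (k in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(k))[1:n]  # 1 = predominant animal
    n_pred <- sum(bits)
    prob <- q^n_pred * (1 - q)^(n - n_pred)
    if (2 * n_pred > n) {
      p <- p + prob
    } else if (2 * n_pred == n) {
      p <- p + 0.5 * prob
    }
  }
  p
}

# Majority probability via an explicit choose() sum (independent of the
# dbinom-based implementation; cross-checked against enumeration for small n).
binom_correct_prob <- function(n, q) {
  if (n == 0) return(0.5)
  i <- 0:n
  pmf <- choose(n, i) * q^i * (1 - q)^(n - i)
  sum(pmf[2 * i > n]) + 0.5 * sum(pmf[2 * i == n])
}

# Brute-force argmax of the expected gain over n = 0..20.
brute_force_optimal_n <- function(q, c) {
  g <- vapply(0:20, function(n) (100 - n * c) * binom_correct_prob(n, q),
              numeric(1))
  # smallest n attaining the maximum (to rounding)
  which(g > max(g) - 1e-9)[1] - 1L
}

# Random natural-scale parameters in plausible ranges for any model.
random_params <- function(model, sd = 1) {
  if (!inherits(model, "beads_model")) model <- beads_model(model)
  vals <- stats::rnorm(length(model$par_names), 0, sd)
  names(vals) <- model$par_names
  logit_pars <- model$par_transforms == "logit"
  vals[logit_pars] <- stats::runif(sum(logit_pars))
  vals
}

# A single-trial context with a fixed sequence.
fixed_trial <- function(stimuli = strrep("D", 20), cost_level = "low",
                        evidence_level = "high", n_samples = NA) {
  cond <- beads_condition(cost_level, evidence_level)
  list(stimuli = stimuli, c = cond$c, q = cond$q, n_samples = n_samples)
}

# Natural-scale NT-like parameter point estimate (group means).
nt_point_params <- function(model = "CostEvidence") {
  m <- beads_model(model)
  full <- transform_params(beads_model("CostEvidence"),
                           default_group_params("NT")$mean)
  out <- full[intersect(m$par_names, names(full))]
  missing <- setdiff(m$par_names, names(out))
  extra <- stats::setNames(rep(0.5, length(missing)), missing)
  c(out, extra)[m$par_names]
}

# Tiny canonical trial table built by hand (no simulation).
tiny_trial_table <- function(n_samples, cost_level = "high",
                             evidence_level = "low", id = "S001",
                             group = "A") {
  cond <- beads_condition(cost_level, evidence_level)
  k <- length(n_samples)
  df <- data.frame(
    participant_id = rep(id, k), group = rep(group, k),
    block_index = rep(1L, k),
    cost_level = rep(cost_level, k), evidence_level = rep(evidence_level, k),
    trial_index = seq_len(k), n_samples = n_samples,
    stimuli = rep(strrep("D", 20), k), choice = rep("dog", k),
    correct = rep(1L, k),
    stringsAsFactors = FALSE
  )
  df$credits <- 100 * df$correct - cond$c * df$n_samples
  df
}
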