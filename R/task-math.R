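#' Task conditions
#'
#' The bead task crosses three sampling-cost levels (0, 1 or 4 credits per
#' animal sampled) with two evidence-strength levels (the predominant animal
#' appears with probability q = 0.6 or q = 0.8). A correct island judgment is
#' worth 100 credits and at most 20 animals can be sampled per trial.
#'
#' @param cost_level One of `"zero"`, `"low"`, `"high"`.
#' @param evidence_level One of `"low"`, `"high"`.
#' @return A `beads_condition` object: list with `cost_level`, `c` (unit cost
#'   in credits), `evidence_level`, `q` (predominant-animal proportion),
#'   `max_samples` and `reward`.
#' @examples
#' beads_condition("high", "low")  # c = 4, q = 0.6
#' @export
beads_condition <- function(cost_level = c("zero", "low", "high"),
                            evidence_level = c("low", "high")) {
  cost_level <- match.arg(cost_level)
  evidence_level <- match.arg(evidence_level)
  structure(
    list(
      cost_level = cost_level,
      c = cost_from_level(cost_level),
      evidence_level = evidence_level,
      q = q_from_level(evidence_level),
      max_samples = 20L,
      reward = 100
    ),
    class = "beads_condition"
  )
}

cost_from_level <- function(level) {
  unname(c(zero = 0, low = 1, high = 4)[level])
}

q_from_level <- function(level) {
  unname(c(low = 0.6, high = 0.8)[level])
}

#' All six task conditions
#'
#' @return A data frame with one row per cost x evidence cell and columns
#'   `cost_level`, `c`, `evidence_level`, `q`.
#' @export
beads_conditions <- function() {
  grid <- expand.grid(
    cost_level = c("zero", "low", "high"),
    evidence_level = c("low", "high"),
    stringsAsFactors = FALSE
  )
  grid$c <- cost_from_level(grid$cost_level)
  grid$q <- q_from_level(grid$evidence_level)
  grid[, c("cost_level", "c", "evidence_level", "q")]
}

check_nq <- function(n, q, max_samples = 20L) {
  if (any(!is.finite(n)) || any(n < 0) || any(n > max_samples) ||
      any(n != floor(n))) {
    stop("`n` must be an integer in [0, ", max_samples, "]", call. = FALSE)
  }
  if (any(!is.finite(q)) || any(q <= 0) || any(q >= 1)) {
    stop("`q` must lie strictly within (0, 1)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Probability of a correct majority judgment
#'
#' Probability that a judgment based on the majority animal among `n`
#' independent draws (each showing the predominant animal with probability
#' `q`) is correct, with ties resolved by a fair coin. For `n = 0` the
#' judgment is a pure guess and the probability is exactly 1/2.
#'
#' Computed by exact binomial summation: P(strict majority) + P(tie)/2.
#'
#' @param n Number of samples drawn, integer in 0..20 (vectorised).
#' @param q Proportion of the predominant animal, in (0.5, 1).
#' @return Probability of a correct judgment.
#' @examples
#' correct_prob(0, 0.8)  # 0.5
#' correct_prob(3, 0.6)  # 0.648
#' @export
correct_prob <- function(n, q) {
  check_nq(n, q)
  if (length(q) == 1L) q <- rep(q, length(n))
  if (length(n) == 1L) n <- rep(n, length(q))
  vapply(seq_along(n), function(i) correct_prob1(n[i], q[i]), numeric(1))
}

correct_prob1 <- function(n, q) {
  if (n == 0L) return(0.5)
  k <- seq_len(n)  # counts of the predominant animal
  p_strict <- sum(stats::dbinom(k[2 * k > n], n, q))
  p_tie <- if (n %% 2 == 0) stats::dbinom(n / 2, n, q) else 0
  p_strict + 0.5 * p_tie
}

#' Expected gain of sampling n animals
#'
#' Expected credits earned on a trial with `n` samples: the 100-credit reward
#' discounted by the per-sample cost, weighted by the probability of judging
#' correctly, `(100 - n c) p(n | q)`.
#'
#' @inheritParams correct_prob
#' @param c Unit sampling cost in credits (>= 0).
#' @param reward Credits for a correct judgment (default 100).
#' @return Expected gain in credits.
#' @examples
#' expected_gain(1, 0.8, 4)  # 76.8
#' @export
expected_gain <- function(n, q, c, reward = 100) {
  if (any(!is.finite(c)) || any(c < 0)) stop("`c` must be >= 0", call. = FALSE)
  (reward - n * c) * correct_prob(n, q)
}

#' Reward-maximising sample number
#'
#' The number of samples n in 0..20 that maximises the expected gain; exact
#' ties are broken towards the smaller n (fewer samples weakly dominate at
#' equal gain).
#'
#' @inheritParams expected_gain
#' @param max_samples Largest allowed sample number (default 20).
#' @return Integer sample number.
#' @examples
#' optimal_n(0.8, 4)  # 3
#' @export
optimal_n <- function(q, c, max_samples = 20L, reward = 100) {
  g <- expected_gain(0:max_samples, q, c, reward = reward)
  which.max(g) - 1L  # which.max takes the first (smallest-n) maximum
}

#' Full gain profile for one condition
#'
#' @inheritParams optimal_n
#' @return A data frame with columns `n`, `p_correct`, `expected_gain`, and
#'   attributes `optimal_n` and `max_gain`.
#' @export
gain_profile <- function(q, c, max_samples = 20L, reward = 100) {
  n <- 0:max_samples
  out <- data.frame(
    n = n,
    p_correct = correct_prob(n, q),
    expected_gain = expected_gain(n, q, c, reward = reward)
  )
  n_star <- optimal_n(q, c, max_samples, reward)
  attr(out, "optimal_n") <- n_star
  attr(out, "max_gain") <- out$expected_gain[n_star + 1L]
  out
}

#' Sampling efficiency
#'
#' Expected gain at the observed sample number divided by the maximum
#' expected gain attainable in the condition. Equals 1 iff the observed
#' sample number attains the maximum.
#'
#' @param n_obs Observed sample number(s), integer in 0..20.
#' @inheritParams optimal_n
#' @return Efficiency ratio in (0, 1].
#' @examples
#' efficiency(0, 0.6, 4)  # 50 / 57.6
#' @export
efficiency <- function(n_obs, q, c, max_samples = 20L, reward = 100) {
  max_gain <- expected_gain(optimal_n(q, c, max_samples, reward), q, c, reward)
  if (max_gain <= 0) stop("invalid condition: maximum expected gain <= 0", call. = FALSE)
  expected_gain(n_obs, q, c, reward = reward) / max_gain
}

#' Signed sampling deviation
#'
#' Observed sample number minus the reward-maximising sample number; negative
#' values indicate undersampling.
#'
#' @inheritParams efficiency
#' @return Signed integer deviation.
#' @export
signed_deviation <- function(n_obs, q, c, max_samples = 20L, reward = 100) {
  check_nq(n_obs, q)
  n_obs - optimal_n(q, c, max_samples, reward)
}
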