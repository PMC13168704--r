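# Six stopping-rule models for the bead task.
#
# At every decision point j = 0..19 (after having seen j animals) the agent
# stops with a probability given by a logistic function of decision variables
# (one-stage models), or by a two-stage scheme in which a first-stage stop
# decision may be reconsidered with a condition-specific "second-thought"
# probability: p = p1 + (1 - p1) * p_sec * p2. At j = 20 stopping is forced.

DV_NAMES <- c("intercept", "cost_low", "cost_high", "draws", "cumu_cost",
              "unit_evid", "abs_cumu_info", "total_log_evid",
              "last_draw", "last_correct")

COST_DVS <- c("intercept", "cost_low", "cost_high", "draws", "cumu_cost")
EVID_DVS <- c("intercept", "unit_evid", "abs_cumu_info", "total_log_evid",
              "last_draw", "last_correct")

BETA_FOR_DV <- c(
  intercept = "beta_0", cost_low = "beta_L0", cost_high = "beta_H0",
  draws = "beta_draw", cumu_cost = "beta_cumu_cost",
  unit_evid = "beta_unit_evid", abs_cumu_info = "beta_abs_cumu_info",
  total_log_evid = "beta_total_log_evid",
  last_draw = "beta_last_draw", last_correct = "beta_last_correct"
)

#' Names of the six stopping models
#' @return Character vector of model names.
#' @export
beads_models <- function() {
  c("CostOnly", "CostEvidence",
    "Cost_Ccond_Evidence", "Cost_Econd_Evidence",
    "Evidence_Ccond_Cost", "Evidence_Econd_Cost")
}

#' Retrieve a stopping-model specification
#'
#' The six models differ in which decision variables (DVs) enter each stage
#' and, for the two-stage models, on what the second-thought probability is
#' conditioned:
#' * `CostOnly` — one stage; cost-related DVs (intercept, low/high-cost
#'   dummies, samples drawn, cumulative cost).
#' * `CostEvidence` — one stage; cost-related plus decayed evidence-related
#'   DVs (unit log evidence, |decayed cumulative information|, total log
#'   evidence, previous trial's sample number and correctness).
#' * `Cost_Ccond_Evidence` / `Cost_Econd_Evidence` — stage 1 cost DVs,
#'   stage 2 evidence DVs; second-thought probability per cost condition /
#'   per evidence condition.
#' * `Evidence_Ccond_Cost` / `Evidence_Econd_Cost` — stage 1 evidence DVs,
#'   stage 2 cost DVs; second-thought probability per cost / evidence
#'   condition.
#'
#' @param name One of [beads_models()].
#' @return A `beads_model` object: list with `name`, `stages`, `stage1`,
#'   `stage2` (DV names), `sec_cond` (`"none"`, `"cost"`, `"evidence"`),
#'   `uses_alpha`, `par_names` and `par_transforms` (`"identity"` or
#'   `"logit"`, giving the map from the unconstrained fitting scale).
#' @export
beads_model <- function(name) {
  name <- match.arg(name, beads_models())
  spec <- switch(name,
    CostOnly = list(stage1 = COST_DVS, stage2 = character(), sec = "none",
                    alpha = FALSE),
    CostEvidence = list(stage1 = c(COST_DVS, setdiff(EVID_DVS, "intercept")),
                        stage2 = character(), sec = "none", alpha = TRUE),
    Cost_Ccond_Evidence = list(stage1 = COST_DVS, stage2 = EVID_DVS,
                               sec = "cost", alpha = TRUE),
    Cost_Econd_Evidence = list(stage1 = COST_DVS, stage2 = EVID_DVS,
                               sec = "evidence", alpha = TRUE),
    Evidence_Ccond_Cost = list(stage1 = EVID_DVS, stage2 = COST_DVS,
                               sec = "cost", alpha = TRUE),
    Evidence_Econd_Cost = list(stage1 = EVID_DVS, stage2 = COST_DVS,
                               sec = "evidence", alpha = TRUE)
  )
  two_stage <- length(spec$stage2) > 0L
  par_names <- if (!two_stage) {
    unname(BETA_FOR_DV[spec$stage1])
  } else {
    c(paste0("s1_", BETA_FOR_DV[spec$stage1]),
      paste0("s2_", BETA_FOR_DV[spec$stage2]))
  }
  if (spec$alpha) par_names <- c(par_names, "alpha_decay")
  sec_names <- switch(spec$sec,
    none = character(),
    cost = c("p_sec_zero", "p_sec_low", "p_sec_high"),
    evidence = c("p_sec_lowev", "p_sec_highev")
  )
  par_names <- c(par_names, sec_names)
  transforms <- ifelse(grepl("^(alpha_|p_sec_)", par_names), "logit", "identity")
  structure(
    list(name = name, stages = if (two_stage) 2L else 1L,
         stage1 = spec$stage1, stage2 = spec$stage2, sec_cond = spec$sec,
         uses_alpha = spec$alpha, par_names = par_names,
         par_transforms = stats::setNames(transforms, par_names)),
    class = "beads_model"
  )
}

check_params <- function(model, params) {
  if (!inherits(model, "beads_model")) model <- beads_model(model)
  missing <- setdiff(model$par_names, names(params))
  if (length(missing)) {
    stop("parameters missing for model ", model$name, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(unlist(params[model$par_names])))) {
    stop("non-finite parameter values", call. = FALSE)
  }
  if (model$uses_alpha) {
    a <- params[["alpha_decay"]]
    if (a < 0 || a > 1) stop("alpha_decay must lie in [0, 1]", call. = FALSE)
  }
  sec <- params[grepl("^p_sec_", model$par_names)]
  if (length(sec) && (any(unlist(sec) < 0) || any(unlist(sec) > 1))) {
    stop("second-thought probabilities must lie in [0, 1]", call. = FALSE)
  }
  model
}

# Map stimuli given in any accepted encoding to signed integers
# (+1 = predominant-side animal "dog", -1 = "cat").
stimuli_to_signed <- function(stimuli) {
  if (is.numeric(stimuli)) {
    if (length(stimuli) && !all(stimuli %in% c(-1, 1))) {
      stop("numeric stimuli must be coded +1/-1", call. = FALSE)
    }
    return(as.integer(stimuli))
  }
  if (is.character(stimuli) && length(stimuli) == 1L && nchar(stimuli) > 1L) {
    stimuli <- strsplit(stimuli, "")[[1]]
  }
  code <- c(dog = 1L, cat = -1L, D = 1L, C = -1L, d = 1L, c = -1L)
  out <- code[as.character(stimuli)]
  if (any(is.na(out))) stop("unrecognised stimulus symbols", call. = FALSE)
  unname(out)
}

signed_to_string <- function(s) {
  paste(ifelse(s > 0, "D", "C"), collapse = "")
}

#' Decayed cumulative information
#'
#' Leaky running difference between the counts of the two animal types:
#' CI_0 = 0 and CI_j = alpha CI_(j-1) + 1 after a dog, - 1 after a cat.
#' alpha = 1 gives the plain count difference; alpha = 0 keeps only the most
#' recent sample.
#'
#' @param stimuli Stimulus prefix: character vector of `"dog"`/`"cat"` (or
#'   `"D"`/`"C"`, or one compact string), or signed +1/-1 integers.
#' @param alpha Decay parameter in \[0, 1\].
#' @return The decayed cumulative information after the full prefix.
#' @examples
#' decayed_ci(c("dog", "dog"), 0.5)  # 1.5
#' @export
decayed_ci <- function(stimuli, alpha) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]", call. = FALSE)
  }
  utils::tail(ci_path(stimuli_to_signed(stimuli), alpha), 1)
}

# CI_j for j = 0..length(s); element j+1 is the value after j samples.
ci_path <- function(s, alpha) {
  ci <- numeric(length(s) + 1L)
  for (j in seq_along(s)) ci[j + 1L] <- alpha * ci[j] + s[j]
  ci
}

#' Decision variables at every decision point of a trial
#'
#' @param stimuli Stimulus sequence (see [decayed_ci()] for encodings).
#' @param c Unit sampling cost in credits.
#' @param q Predominant-animal proportion.
#' @param alpha Decay parameter for cumulative information.
#' @param last_draw Previous trial's sample number (0 at the first trial).
#' @param last_correct Previous trial's correctness coded +1 correct / -1
#'   incorrect (0 at the first trial).
#' @param n_points Number of decision points to tabulate (rows j = 0 ..
#'   n_points); defaults to the stimulus length.
#' @return Data frame with one row per decision point `j` and the DV columns
#'   `intercept`, `cost_low`, `cost_high`, `draws`, `cumu_cost`, `unit_evid`,
#'   `abs_cumu_info`, `total_log_evid`, `last_draw`, `last_correct`.
#' @export
build_dvs <- function(stimuli, c, q, alpha = 1, last_draw = 0,
                      last_correct = 0, n_points = NULL) {
  s <- stimuli_to_signed(stimuli)
  if (is.null(n_points)) n_points <- length(s)
  if (n_points > length(s)) stop("n_points exceeds stimulus length", call. = FALSE)
  j <- 0:n_points
  ci <- ci_path(s, alpha)[j + 1L]
  unit_evid <- log(q / (1 - q))
  data.frame(
    j = j,
    intercept = 1,
    cost_low = as.numeric(c == 1),
    cost_high = as.numeric(c == 4),
    draws = j,
    cumu_cost = c * j,
    unit_evid = unit_evid,
    abs_cumu_info = abs(ci),
    total_log_evid = unit_evid * abs(ci),
    last_draw = last_draw,
    last_correct = last_correct
  )
}

stage_linpred <- function(dv_names, betas, dvs) {
  X <- as.matrix(dvs[, dv_names, drop = FALSE])
  drop(X %*% betas[dv_names])
}

#' Per-decision stopping probability
#'
#' One-stage models: `plogis(sum_k beta_k DV_k)`. Two-stage models:
#' `p1 + (1 - p1) p_sec p2`, where `p_sec` is selected by the trial's cost or
#' evidence condition according to the model.
#'
#' @param model A [beads_model()] or model name.
#' @param params Named numeric vector/list of parameters on their natural
#'   scale (see `beads_model(name)$par_names`).
#' @param dvs Decision-variable table from [build_dvs()].
#' @return Vector of stopping probabilities, one per row of `dvs`.
#' @export
stop_prob <- function(model, params, dvs) {
  model <- check_params(model, params)
  params <- unlist(params)
  if (model$stages == 1L) {
    b <- stats::setNames(params[BETA_FOR_DV[model$stage1]], model$stage1)
    return(stats::plogis(stage_linpred(model$stage1, b, dvs)))
  }
  b1 <- stats::setNames(params[paste0("s1_", BETA_FOR_DV[model$stage1])],
                        model$stage1)
  b2 <- stats::setNames(params[paste0("s2_", BETA_FOR_DV[model$stage2])],
                        model$stage2)
  p1 <- stats::plogis(stage_linpred(model$stage1, b1, dvs))
  p2 <- stats::plogis(stage_linpred(model$stage2, b2, dvs))
  p_sec <- if (model$sec_cond == "cost") {
    ifelse(dvs$cost_high == 1, params[["p_sec_high"]],
           ifelse(dvs$cost_low == 1, params[["p_sec_low"]],
                  params[["p_sec_zero"]]))
  } else {
    # high evidence iff unit log evidence corresponds to q = 0.8
    ifelse(dvs$unit_evid > log(0.7 / 0.3), params[["p_sec_highev"]],
           params[["p_sec_lowev"]])
  }
  p1 + (1 - p1) * p_sec * p2
}

default_prev <- list(last_draw = 0, last_correct = 0)

trial_stop_probs <- function(model, params, trial, prev = default_prev,
                             n_points = 20L) {
  alpha <- if (isTRUE(model$uses_alpha)) unlist(params)[["alpha_decay"]] else 1
  dvs <- build_dvs(trial$stimuli, c = trial$c, q = trial$q, alpha = alpha,
                   last_draw = prev$last_draw,
                   last_correct = prev$last_correct,
                   n_points = n_points)
  stop_prob(model, params, dvs)
}

#' Log-likelihood of one trial's stopping time
#'
#' The stopping time has hazard `p_j` at decision points j = 0..19 and a
#' forced stop at j = 20. A trial with `n < 20` samples contributes
#' `sum_(j<n) log(1 - p_j) + log(p_n)`; a trial with `n = 20` contributes
#' only the continuation terms (the forced stop carries no probability).
#'
#' @inheritParams stop_prob
#' @param trial List with `stimuli`, `c`, `q` and `n_samples`.
#' @param prev List with `last_draw` and `last_correct` from the previous
#'   trial (defaults encode "no previous trial").
#' @return Log-likelihood (scalar).
#' @export
trial_loglik <- function(model, params, trial, prev = default_prev) {
  model <- check_params(model, params)
  n <- trial$n_samples
  if (!is.finite(n) || n < 0 || n > 20) stop("n_samples outside 0..20", call. = FALSE)
  p <- trial_stop_probs(model, params, trial, prev,
                        n_points = min(n, 19L))
  if (any(!is.finite(p))) stop("non-finite stop probabilities", call. = FALSE)
  if (n == 20L) sum(log1p(-p)) else sum(log1p(-p[seq_len(n)])) + log(p[n + 1L])
}

#' Analytic stopping-time distribution for one stimulus sequence
#'
#' @inheritParams trial_loglik
#' @param stimuli Full 20-symbol stimulus sequence.
#' @param condition A [beads_condition()] (or any list with `c` and `q`).
#' @return Probability vector over n = 0..20 (sums to 1).
#' @export
stopping_distribution <- function(model, params, stimuli, condition,
                                  prev = default_prev) {
  model <- check_params(model, params)
  trial <- list(stimuli = stimuli, c = condition$c, q = condition$q)
  p <- trial_stop_probs(model, params, trial, prev, n_points = 19L)
  surv <- cumprod(1 - p)            # P(N > j), j = 0..19
  c(p * c(1, surv[1:19]), surv[20])
}

#' Dataset log-likelihood with pointwise trial contributions
#'
#' Sums [trial_loglik()] over all trials of all children, carrying the
#' previous-trial decision variables in experiment order within each child.
#'
#' @inheritParams stop_prob
#' @param params_per_child Named list (by participant id) of parameter
#'   vectors, or a single parameter vector shared by all children.
#' @param dataset Trial data frame in the canonical schema (see
#'   [read_trials()]); trials must be ordered by `trial_index` within child.
#' @return List with `total` (sum) and `pointwise` (per-trial log-likelihood
#'   vector aligned with the rows of `dataset`).
#' @export
dataset_loglik <- function(model, params_per_child, dataset) {
  if (!inherits(model, "beads_model")) model <- beads_model(model)
  if (nrow(dataset) == 0L) return(list(total = 0, pointwise = numeric()))
  dataset <- ensure_cq(dataset)
  pointwise <- numeric(nrow(dataset))
  for (id in unique(dataset$participant_id)) {
    idx <- which(dataset$participant_id == id)
    ti <- dataset$trial_index[idx]
    if (is.unsorted(ti, strictly = TRUE)) {
      stop("trials of participant ", id, " are not in increasing trial order",
           call. = FALSE)
    }
    params <- if (is.list(params_per_child) && !is.null(names(params_per_child)) &&
                  id %in% names(params_per_child)) {
      params_per_child[[as.character(id)]]
    } else {
      params_per_child
    }
    prev <- default_prev
    for (r in idx) {
      trial <- list(stimuli = dataset$stimuli[r], c = dataset$c[r],
                    q = dataset$q[r], n_samples = dataset$n_samples[r])
      pointwise[r] <- trial_loglik(model, params, trial, prev)
      prev <- list(last_draw = dataset$n_samples[r],
                   last_correct = if (dataset$correct[r] == 1) 1 else -1)
    }
  }
  list(total = sum(pointwise), pointwise = pointwise)
}
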