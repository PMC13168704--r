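# Synthetic-data generator: experiment designs, stimulus sequences, model
# agents, cohorts, and one-at-a-time parameter sweeps.

# Evaluate `expr` under a temporary RNG seed without disturbing the caller's
# RNG state; seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Build an experiment design
#'
#' Three cost blocks (order permuted by seed), each containing the two
#' evidence mini-blocks in random order, with `trials_per_miniblock` trials
#' each: 16 gives the standard 96-trial session, 8 the 48-trial short form.
#'
#' @param trials_per_miniblock Trials per cost x evidence cell (>= 1).
#' @param seed Integer seed for the block order (NULL = current RNG stream).
#' @return Data frame with columns `block_index`, `cost_level`,
#'   `evidence_level`, `trial_index`, `c`, `q`; each of the six conditions
#'   appears in exactly one mini-block.
#' @export
make_design <- function(trials_per_miniblock = 16L, seed = NULL) {
  if (!is.finite(trials_per_miniblock) || trials_per_miniblock < 1) {
    stop("trials_per_miniblock must be >= 1", call. = FALSE)
  }
  with_seed(seed, {
    cost_order <- sample(c("zero", "low", "high"))
    rows <- list()
    block <- 0L
    for (cl in cost_order) {
      for (ev in sample(c("low", "high"))) {
        block <- block + 1L
        rows[[block]] <- data.frame(
          block_index = block, cost_level = cl, evidence_level = ev,
          stringsAsFactors = FALSE
        )[rep(1L, trials_per_miniblock), ]
      }
    }
    design <- do.call(rbind, rows)
    design$trial_index <- seq_len(nrow(design))
    design$c <- cost_from_level(design$cost_level)
    design$q <- q_from_level(design$evidence_level)
    rownames(design) <- NULL
    design
  })
}

#' Generate one 20-animal stimulus sequence
#'
#' Each of the 20 positions independently shows the predominant animal of the
#' true island with probability `q` (i.i.d. draws with replacement; the full
#' sequence includes animals beyond the stopping point, as would have been
#' shown).
#'
#' @param q Predominant-animal proportion in (0, 1).
#' @param true_island `"dog"` or `"cat"`: which animal predominates.
#' @param seed Optional integer seed.
#' @return Character scalar of 20 symbols over `D`/`C` (dog/cat).
#' @export
gen_stimuli <- function(q, true_island = c("dog", "cat"), seed = NULL) {
  if (!is.finite(q) || q <= 0 || q >= 1) stop("q must lie in (0, 1)", call. = FALSE)
  true_island <- match.arg(true_island)
  with_seed(seed, {
    predominant <- stats::rbinom(20L, 1L, q) == 1L
    shown_dog <- if (true_island == "dog") predominant else !predominant
    paste(ifelse(shown_dog, "D", "C"), collapse = "")
  })
}

# Attach true islands and stimulus sequences to a design.
generate_trials <- function(design, seed = NULL) {
  with_seed(seed, {
    design$true_island <- sample(c("dog", "cat"), nrow(design), replace = TRUE)
    design$stimuli <- vapply(seq_len(nrow(design)), function(i) {
      gen_stimuli(design$q[i], design$true_island[i])
    }, character(1))
    design
  })
}

#' Simulate a model agent on a set of trials
#'
#' Runs the stopping model over the trials in order: at each decision point
#' j = 0..19 the agent stops with the model's hazard probability (forced stop
#' at j = 20), then judges by the majority animal seen (tie: fair coin).
#' Previous-trial decision variables are carried across consecutive trials.
#'
#' @inheritParams stop_prob
#' @param trials Data frame of trials with `cost_level`, `evidence_level`,
#'   `stimuli` and `true_island` columns, in experiment order (see
#'   [make_design()] / `generate_trials`); if `stimuli` is absent it is
#'   generated.
#' @param seed Optional integer seed.
#' @return The `trials` data frame with `n_samples`, `choice`, `correct` and
#'   `credits` filled in.
#' @export
simulate_agent <- function(model, params, trials, seed = NULL) {
  model <- check_params(model, params)
  trials <- ensure_cq(trials)
  if (is.null(trials$stimuli)) trials <- generate_trials(trials, seed = seed)
  with_seed(seed, {
    n_tr <- nrow(trials)
    n_samples <- integer(n_tr)
    choice <- character(n_tr)
    correct <- integer(n_tr)
    prev <- default_prev
    for (i in seq_len(n_tr)) {
      trial <- list(stimuli = trials$stimuli[i], c = trials$c[i], q = trials$q[i])
      p <- trial_stop_probs(model, params, trial, prev, n_points = 19L)
      u <- stats::runif(20L)
      hit <- which(u < p)
      n <- if (length(hit)) hit[1L] - 1L else 20L
      s <- stimuli_to_signed(trials$stimuli[i])
      seen <- if (n > 0) sum(s[seq_len(n)]) else 0L
      ch <- if (seen > 0) "dog" else if (seen < 0) "cat" else {
        sample(c("dog", "cat"), 1L)
      }
      n_samples[i] <- n
      choice[i] <- ch
      correct[i] <- as.integer(ch == trials$true_island[i])
      prev <- list(last_draw = n, last_correct = if (correct[i] == 1) 1 else -1)
    }
    trials$n_samples <- n_samples
    trials$choice <- choice
    trials$correct <- correct
    trials$credits <- 100 * correct - trials$c * n_samples
    trials
  })
}

#' Default generating parameters for synthetic groups
#'
#' Group-level means and between-child SDs for the `CostEvidence` model, on
#' the unconstrained fitting scale (identity for the betas, log-odds for
#' `alpha_decay`). The `"NT"` set emulates neurotypical-like children
#' (moderate stopping tendency, strong sensitivity to accrued samples, costs
#' and evidence, negative last-trial carry-over, near-uniform evidence
#' weighting); the `"ASD"` set emulates autistic-like children (weaker
#' stopping tendency at zero cost, stronger nominal-cost offsets, weaker
#' dynamic sensitivities, negligible last-trial carry-over, recency-weighted
#' evidence).
#'
#' @param group `"NT"` or `"ASD"`.
#' @return List with numeric vectors `mean` and `sd` named by parameter.
#' @export
default_group_params <- function(group = c("NT", "ASD")) {
  group <- match.arg(group)
  sd <- c(beta_0 = 1.0, beta_L0 = 0.5, beta_H0 = 0.6,
          beta_draw = 0.05, beta_cumu_cost = 0.02,
          beta_unit_evid = 0.25, beta_abs_cumu_info = 0.08,
          beta_total_log_evid = 0.06, beta_last_draw = 0.03,
          beta_last_correct = 0.15, alpha_decay = 0.7)
  mean <- if (group == "NT") {
    c(beta_0 = -4.5, beta_L0 = 1.0, beta_H0 = 1.9,
      beta_draw = 0.12, beta_cumu_cost = 0.05,
      beta_unit_evid = 0.4, beta_abs_cumu_info = 0.25,
      beta_total_log_evid = 0.15, beta_last_draw = -0.06,
      beta_last_correct = 0.15, alpha_decay = stats::qlogis(0.9))
  } else {
    c(beta_0 = -5.7, beta_L0 = 1.4, beta_H0 = 2.6,
      beta_draw = 0.05, beta_cumu_cost = 0.02,
      beta_unit_evid = 0.4, beta_abs_cumu_info = 0.10,
      beta_total_log_evid = 0.10, beta_last_draw = -0.01,
      beta_last_correct = 0.15, alpha_decay = stats::qlogis(0.55))
  }
  list(mean = mean, sd = sd)
}

#' Map parameters between the unconstrained and natural scales
#'
#' Betas are unchanged; `alpha_decay` and second-thought probabilities map
#' through the logistic function (and its inverse).
#'
#' @inheritParams stop_prob
#' @param unconstrained,natural Named parameter vector.
#' @return Named parameter vector on the other scale.
#' @export
transform_params <- function(model, unconstrained) {
  tr <- model$par_transforms[names(unconstrained)]
  out <- unconstrained
  out[tr == "logit"] <- stats::plogis(unconstrained[tr == "logit"])
  out
}

#' @rdname transform_params
#' @export
untransform_params <- function(model, natural) {
  tr <- model$par_transforms[names(natural)]
  out <- natural
  out[tr == "logit"] <- stats::qlogis(natural[tr == "logit"])
  out
}

#' Simulate a cohort of children
#'
#' Child-level parameters are drawn from group-level normal distributions on
#' the unconstrained scale (constrained parameters are mapped through their
#' logistic transform), then each child is simulated on their own design.
#'
#' @inheritParams stop_prob
#' @param group_level List with `mean` and `sd` vectors named by model
#'   parameter, on the unconstrained scale (see [default_group_params()]).
#' @param n_children Number of children (>= 1).
#' @param seed Integer seed; recorded in the result for exact replay.
#' @param trials_per_miniblock 16 (96 trials) or 8 (48-trial short form).
#' @param group_label Group label stored in the trial table.
#' @param id_prefix Prefix for participant ids (use distinct prefixes when
#'   combining cohorts into one dataset).
#' @return A `beads_cohort`: list with `trials` (canonical trial table for
#'   all children), `params` (child-by-parameter natural-scale matrix),
#'   `params_unconstrained`, `group_level`, `model`, `seed`.
#' @export
make_cohort <- function(model, group_level, n_children, seed = NULL,
                        trials_per_miniblock = 16L, group_label = "synthetic",
                        id_prefix = "S") {
  if (!inherits(model, "beads_model")) model <- beads_model(model)
  if (n_children < 1) stop("n_children must be >= 1", call. = FALSE)
  mu <- group_level$mean[model$par_names]
  sd <- group_level$sd[model$par_names]
  if (anyNA(mu) || anyNA(sd)) {
    stop("group_level must provide mean and sd for every model parameter",
         call. = FALSE)
  }
  if (any(sd < 0)) stop("group-level SDs must be >= 0", call. = FALSE)
  with_seed(seed, {
    P <- length(mu)
    unc <- matrix(stats::rnorm(n_children * P, rep(mu, each = n_children),
                               rep(sd, each = n_children)),
                  nrow = n_children, dimnames = list(NULL, model$par_names))
    nat <- unc
    for (i in seq_len(n_children)) {
      nat[i, ] <- transform_params(model, unc[i, ])
    }
    all_trials <- vector("list", n_children)
    for (i in seq_len(n_children)) {
      trials <- generate_trials(make_design(trials_per_miniblock))
      trials <- simulate_agent(model, nat[i, ], trials)
      trials$participant_id <- sprintf("%s%03d", id_prefix, i)
      trials$group <- group_label
      all_trials[[i]] <- trials
    }
    trials <- do.call(rbind, all_trials)
    cols <- c("participant_id", "group", "block_index", "cost_level",
              "evidence_level", "trial_index", "true_island", "stimuli",
              "n_samples", "choice", "correct", "credits", "c", "q")
    structure(
      list(trials = trials[, cols], params = nat, params_unconstrained = unc,
           group_level = list(mean = mu, sd = sd), model = model$name,
           seed = seed),
      class = "beads_cohort"
    )
  })
}

#' One-at-a-time parameter sweep
#'
#' Varies one parameter over a grid while holding the others at `base`,
#' simulating the agent repeatedly on a fixed set of stimulus sequences, and
#' reports per-condition behavioural metrics for each grid value.
#'
#' @inheritParams simulate_agent
#' @param base Named base parameter vector (natural scale).
#' @param name Parameter to vary (must be a model parameter).
#' @param grid Numeric vector of values (natural scale) within the
#'   parameter's domain.
#' @param trials Fixed trial set with stimulus sequences (reused for every
#'   grid value).
#' @param n_reps Replicate simulation passes per grid value.
#' @param seed Integer seed.
#' @return Data frame: one row per grid value x condition with `value`,
#'   `cost_level`, `evidence_level`, `mean_samples`, `mean_efficiency`,
#'   `sampling_variation`.
#' @export
sweep_parameter <- function(model, base, name, grid, trials, n_reps = 20L,
                            seed = NULL) {
  model <- check_params(model, base)
  if (!name %in% model$par_names) {
    stop("unknown parameter: ", name, call. = FALSE)
  }
  trials <- ensure_cq(trials)
  if (is.null(trials$stimuli)) trials <- generate_trials(trials, seed = seed)
  with_seed(seed, {
    out <- list()
    for (g in seq_along(grid)) {
      pars <- unlist(base)
      pars[name] <- grid[g]
      sims <- lapply(seq_len(n_reps), function(r) {
        simulate_agent(model, pars, trials)
      })
      sim <- do.call(rbind, sims)
      sim$rep <- rep(seq_len(n_reps), each = nrow(trials))
      sim$eff <- vapply(seq_len(nrow(sim)), function(i) {
        efficiency(sim$n_samples[i], sim$q[i], sim$c[i])
      }, numeric(1))
      agg <- stats::aggregate(
        cbind(mean_samples = n_samples, mean_efficiency = eff) ~
          cost_level + evidence_level, data = sim, FUN = mean)
      # inter-trial SD computed within replicate passes, then averaged
      sv <- stats::aggregate(n_samples ~ cost_level + evidence_level + rep,
                             data = sim, FUN = stats::sd)
      sv <- stats::aggregate(n_samples ~ cost_level + evidence_level,
                             data = sv, FUN = mean)
      names(sv)[names(sv) == "n_samples"] <- "sampling_variation"
      agg <- merge(agg, sv, by = c("cost_level", "evidence_level"))
      agg$value <- grid[g]
      agg$parameter <- name
      out[[g]] <- agg
    }
    res <- do.call(rbind, out)
    res[, c("parameter", "value", "cost_level", "evidence_level",
            "mean_samples", "mean_efficiency", "sampling_variation")]
  })
}
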