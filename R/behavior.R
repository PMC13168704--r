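# Behavioural outcome pipeline: per-child condition summaries, mixed-model
# group contrasts, and FDR-corrected parameter-behaviour correlations.

#' Per-child behavioural summaries by condition
#'
#' One row per child x condition with the five modelled outcomes: game
#' credits, accuracy, sampling efficiency, signed deviation from the
#' reward-maximising sample number, and sampling variation (inter-trial SD
#' of sample numbers; undefined and flagged for conditions with < 2 trials).
#' Efficiency and deviation use the [efficiency()] and [signed_deviation()]
#' task mathematics trial-wise.
#'
#' @param dataset Trial data frame in the canonical schema.
#' @return Data frame with `participant_id`, `group`, `cost_level`,
#'   `evidence_level`, `n_trials`, `mean_samples`, `mean_credits`,
#'   `accuracy`, `mean_efficiency`, `mean_signed_deviation`,
#'   `sampling_variation`.
#' @export
summarize_children <- function(dataset) {
  dataset <- ensure_cq(dataset)
  conds <- beads_conditions()
  # trial-wise outcomes from the single task-math source of truth
  opt <- stats::setNames(
    vapply(seq_len(nrow(conds)), function(i) optimal_n(conds$q[i], conds$c[i]),
           integer(1)),
    paste(conds$cost_level, conds$evidence_level))
  key <- paste(dataset$cost_level, dataset$evidence_level)
  if (any(!key %in% names(opt))) stop("unknown condition labels", call. = FALSE)
  eff <- vapply(seq_len(nrow(dataset)), function(i) {
    efficiency(dataset$n_samples[i], dataset$q[i], dataset$c[i])
  }, numeric(1))
  dev <- dataset$n_samples - opt[key]
  split_key <- interaction(dataset$participant_id, dataset$group,
                           dataset$cost_level, dataset$evidence_level,
                           drop = TRUE)
  rows <- lapply(split(seq_len(nrow(dataset)), split_key), function(idx) {
    d <- dataset[idx, ]
    data.frame(
      participant_id = d$participant_id[1],
      group = d$group[1],
      cost_level = d$cost_level[1],
      evidence_level = d$evidence_level[1],
      n_trials = nrow(d),
      mean_samples = mean(d$n_samples),
      mean_credits = mean(d$credits),
      accuracy = mean(d$correct),
      mean_efficiency = mean(eff[idx]),
      mean_signed_deviation = mean(dev[idx]),
      sampling_variation = if (nrow(d) >= 2) stats::sd(d$n_samples) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$cost_level, out$evidence_level), ]
  rownames(out) <- NULL
  out
}

#' Mixed-model group contrasts for a behavioural outcome
#'
#' Fits `outcome ~ group * cost_level * evidence_level` with a per-child
#' random intercept to the child x condition summary table (Satterthwaite
#' degrees of freedom), and returns the fixed-effect tests, estimated
#' marginal means per group x condition, and group contrasts (overall and
#' within cost levels) with single-step multivariate-t adjustment. Cells
#' with an undefined outcome (e.g. sampling variation with < 2 trials) are
#' dropped. A singular random-effect fit falls back to a fixed-effects
#' model, recorded in `$notes`.
#'
#' @param summaries Output of [summarize_children()] (two groups, >= 2
#'   children per group).
#' @param outcome Name of a summary column, e.g. `"mean_efficiency"`.
#' @return List with `model`, `anova`, `emmeans` (group x cost x evidence),
#'   `group_contrasts` (overall and by cost level, mvt-adjusted), `notes`.
#' @export
fit_group_contrasts <- function(summaries, outcome = "mean_efficiency") {
  if (!outcome %in% names(summaries)) {
    stop("unknown outcome: ", outcome, call. = FALSE)
  }
  d <- summaries[!is.na(summaries[[outcome]]), ]
  d$group <- factor(d$group)
  d$cost_level <- factor(d$cost_level, levels = c("zero", "low", "high"))
  d$evidence_level <- factor(d$evidence_level, levels = c("low", "high"))
  d$participant_id <- factor(d$participant_id)
  if (nlevels(d$group) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(unique(d[, c("participant_id", "group")])$group) < 2)) {
    stop("need >= 2 children per group", call. = FALSE)
  }
  d$.y <- d[[outcome]]
  notes <- character()
  fit <- tryCatch(
    lmerTest::lmer(.y ~ group * cost_level * evidence_level +
                     (1 | participant_id), data = d),
    error = function(e) e)
  if (inherits(fit, "error") || lme4::isSingular(fit, tol = 1e-4)) {
    notes <- c(notes, "singular/degenerate random intercept: refit as fixed-effects lm")
    fit <- stats::lm(.y ~ group * cost_level * evidence_level, data = d)
  }
  an <- if (inherits(fit, "lmerModLmerTest")) {
    stats::anova(fit, type = 3)
  } else {
    stats::anova(fit)
  }
  emm <- emmeans::emmeans(fit, ~ group | cost_level * evidence_level)
  overall <- emmeans::emmeans(fit, ~ group)
  by_cost <- emmeans::emmeans(fit, ~ group | cost_level)
  ct_overall <- summary(emmeans::contrast(overall, "pairwise"), adjust = "mvt",
                        infer = TRUE)
  ct_cost <- summary(emmeans::contrast(by_cost, "pairwise"), adjust = "mvt",
                     infer = TRUE)
  list(model = fit, anova = an, emmeans = summary(emm),
       group_contrasts = list(overall = ct_overall, by_cost = ct_cost),
       outcome = outcome, notes = notes)
}

#' Spearman correlations between model parameters and behaviour
#'
#' Rank correlations between child-level posterior-mean parameters and
#' per-child behavioural metrics, with Benjamini-Hochberg FDR adjustment
#' across the requested pairs.
#'
#' @param child_params Data frame with `participant_id` and parameter
#'   columns (e.g. [child_posterior_means()]).
#' @param summaries Output of [summarize_children()]; metrics are averaged
#'   over conditions per child unless `cost_level`/`evidence_level` filters
#'   are given in `pairs`.
#' @param pairs Data frame with columns `parameter` and `metric` (and
#'   optionally `cost_level`, `evidence_level` to restrict the averaging).
#' @return Data frame: `parameter`, `metric`, `n`, `rho`, `p_value`,
#'   `p_adjusted` (BH).
#' @export
correlate_params_behavior <- function(child_params, summaries, pairs) {
  stopifnot(all(c("parameter", "metric") %in% names(pairs)))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    par <- pairs$parameter[i]
    met <- pairs$metric[i]
    if (!par %in% names(child_params)) stop("unknown parameter: ", par, call. = FALSE)
    if (!met %in% names(summaries)) stop("unknown metric: ", met, call. = FALSE)
    s <- summaries
    if (!is.null(pairs$cost_level) && !is.na(pairs$cost_level[i])) {
      s <- s[s$cost_level == pairs$cost_level[i], ]
    }
    if (!is.null(pairs$evidence_level) && !is.na(pairs$evidence_level[i])) {
      s <- s[s$evidence_level == pairs$evidence_level[i], ]
    }
    per_child <- stats::aggregate(s[[met]], list(participant_id = s$participant_id),
                                  mean, na.rm = TRUE)
    merged <- merge(child_params[, c("participant_id", par)], per_child,
                    by = "participant_id")
    merged <- merged[stats::complete.cases(merged), ]
    if (nrow(merged) < 4) stop("fewer than 4 complete pairs", call. = FALSE)
    ct <- suppressWarnings(
      stats::cor.test(merged[[par]], merged$x, method = "spearman"))
    data.frame(parameter = par, metric = met, n = nrow(merged),
               rho = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}
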