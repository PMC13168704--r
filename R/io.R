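# Canonical trial-table IO, validation, run manifests and the CLI surface.

TRIAL_COLUMNS <- c("participant_id", "group", "block_index", "cost_level",
                   "evidence_level", "trial_index", "n_samples", "stimuli",
                   "choice", "correct", "credits")

# Add unit cost `c` and proportion `q` columns if absent ([[ ]]: no partial
# matching against cost_level etc.).
ensure_cq <- function(df) {
  if (is.null(df[["c"]])) df$c <- cost_from_level(df$cost_level)
  if (is.null(df[["q"]])) df$q <- q_from_level(df$evidence_level)
  if (anyNA(df$c) || anyNA(df$q)) {
    stop("unknown cost_level/evidence_level labels", call. = FALSE)
  }
  df
}

validate_trials <- function(df, allow_missing_stimuli = FALSE) {
  problems <- character()
  note <- function(rows, what) {
    if (length(rows)) {
      sprintf("rows %s: %s", paste(utils::head(rows, 5), collapse = ","), what)
    }
  }
  bad_n <- which(!is.finite(df$n_samples) | df$n_samples < 0 |
                   df$n_samples > 20 | df$n_samples != floor(df$n_samples))
  problems <- c(problems, note(bad_n, "n_samples outside 0..20"))
  len <- nchar(df$stimuli)
  bad_s <- which(len != 20L & !(allow_missing_stimuli & len >= df$n_samples))
  problems <- c(problems, note(bad_s, "stimuli not 20 symbols"))
  bad_sym <- which(grepl("[^DC]", df$stimuli))
  problems <- c(problems, note(bad_sym, "stimuli symbols outside {D,C}"))
  bad_cor <- which(!df$correct %in% c(0L, 1L))
  problems <- c(problems, note(bad_cor, "correct not in {0,1}"))
  df <- ensure_cq(df)
  bad_cred <- which(abs(df$credits - (100 * df$correct - df$c * df$n_samples)) > 1e-8)
  problems <- c(problems, note(bad_cred, "credits inconsistent with correct/cost"))
  problems <- problems[lengths(problems) > 0 & nzchar(problems)]
  if (length(problems)) {
    stop("invalid trial table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  df
}

#' Read a trial-level dataset
#'
#' Reads a CSV in the canonical schema (`participant_id`, `group`,
#' `block_index`, `cost_level`, `evidence_level`, `trial_index`,
#' `n_samples`, `stimuli` as a 20-character `D`/`C` string, `choice`,
#' `correct`, `credits`), optionally renaming columns of a foreign file via
#' `column_map`, and validates every invariant with row-level messages.
#'
#' @param path Path to a delimited text file.
#' @param column_map Optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(participant_id = "subj")`.
#' @param allow_missing_stimuli If TRUE, accept stimulus strings shorter than
#'   20 symbols provided they cover the observed samples.
#' @return Validated trial data frame (with derived `c` and `q` columns),
#'   ordered by participant and trial index. Children with fewer than 96
#'   trials are flagged via the `short_form` attribute.
#' @export
read_trials <- function(path, column_map = NULL, allow_missing_stimuli = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(stimuli = "character"))
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      names(df)[names(df) == column_map[[canon]]] <- canon
    }
  }
  missing <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- validate_trials(df, allow_missing_stimuli = allow_missing_stimuli)
  df <- df[order(df$participant_id, df$trial_index), ]
  rownames(df) <- NULL
  counts <- table(df$participant_id)
  attr(df, "short_form") <- names(counts)[counts < 96]
  df
}

#' Write a trial-level dataset
#'
#' @param trials Trial data frame (e.g. `make_cohort(...)$trials`).
#' @param path Output CSV path.
#' @param sidecar Optional list (true parameters, seeds, settings) written as
#'   a JSON sidecar next to the CSV.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, sidecar = NULL) {
  keep <- intersect(c(TRIAL_COLUMNS, "true_island"), names(trials))
  utils::write.csv(trials[, keep], path, row.names = FALSE, quote = FALSE)
  if (!is.null(sidecar)) {
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Build a run manifest
#'
#' @param command Character label of the pipeline step.
#' @param settings List of settings/seeds to record.
#' @return List with command, settings, package version and timestamp.
#' @export
run_manifest <- function(command, settings = list()) {
  list(
    command = command,
    settings = settings,
    package = "beadsampler",
    version = as.character(utils::packageVersion("beadsampler")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

cli_usage <- function() {
  paste(
    "usage: beads.R <command> [options]",
    "commands:",
    "  profile  --out FILE                     gain profiles for all six conditions",
    "  simulate --children N --seed S --out FILE [--group NT|ASD] [--short]",
    "  metrics  --data FILE --out FILE         per-child behavioural summaries",
    "  fit      --data FILE --model NAME --seed S --out PREFIX [--preset desk|full]",
    "  compare  --data FILE --models A,B,... --seed S --out FILE [--preset desk|full]",
    "  sweep    --parameter NAME --grid a,b,c --seed S --out FILE",
    "  sbc      --toy --n N --seed S --out FILE",
    sep = "\n")
}

cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- substring(a, 3)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      opts[[key]] <- TRUE
      i <- i + 1L
    }
  }
  opts
}

#' Command-line entry point
#'
#' Thin dispatcher over the package's functions; see `inst/cli/beads.R` for
#' the executable wrapper. Every artifact is written with a JSON manifest
#' recording the command, settings and seeds.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
beads_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message(cli_usage())
    return(invisible(1L))
  }
  command <- args[1L]
  opts <- tryCatch(cli_opts(args[-1L]), error = function(e) e)
  if (inherits(opts, "error") ||
      !command %in% c("profile", "simulate", "metrics", "fit", "compare",
                      "sweep", "sbc")) {
    message(cli_usage())
    return(invisible(1L))
  }
  seed <- if (!is.null(opts$seed)) as.integer(opts$seed)
  out <- opts$out
  status <- tryCatch({
    switch(command,
      profile = {
        conds <- beads_conditions()
        profs <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
          gp <- gain_profile(conds$q[i], conds$c[i])
          cbind(cost_level = conds$cost_level[i],
                evidence_level = conds$evidence_level[i], gp)
        }))
        utils::write.csv(profs, out, row.names = FALSE)
      },
      simulate = {
        n <- as.integer(opts$children %||% 10L)
        grp <- opts$group %||% "NT"
        tpm <- if (isTRUE(opts$short)) 8L else 16L
        cohort <- make_cohort("CostEvidence", default_group_params(grp), n,
                              seed = seed, trials_per_miniblock = tpm,
                              group_label = grp)
        write_trials(cohort$trials, out, sidecar = list(
          manifest = run_manifest("simulate", list(children = n, seed = seed,
                                                   group = grp)),
          group_level = cohort$group_level,
          params = as.data.frame(cohort$params)))
      },
      metrics = {
        trials <- read_trials(opts$data)
        utils::write.csv(summarize_children(trials), out, row.names = FALSE)
      },
      fit = {
        trials <- read_trials(opts$data)
        fit <- fit_hierarchical(opts$model, trials,
                                mcmc = mcmc_preset(opts$preset %||% "desk"),
                                seed = seed)
        utils::write.csv(as.data.frame(fit$draws$group_mean),
                         paste0(out, "_group_means.csv"), row.names = FALSE)
        jsonlite::write_json(
          list(manifest = run_manifest("fit", list(model = opts$model,
                                                   seed = seed)),
               diagnostics = diagnostics_report(fit)),
          paste0(out, "_diagnostics.json"), auto_unbox = TRUE, digits = NA)
      },
      compare = {
        trials <- read_trials(opts$data)
        models <- strsplit(opts$models, ",")[[1]]
        fits <- lapply(models, function(m) {
          fit_hierarchical(m, trials, mcmc = mcmc_preset(opts$preset %||% "desk"),
                           seed = seed)
        })
        names(fits) <- models
        utils::write.csv(compare_models(fits, seed = seed), out,
                         row.names = FALSE)
      },
      sweep = {
        grid <- as.numeric(strsplit(opts$grid, ",")[[1]])
        base <- transform_params(beads_model("CostEvidence"),
                                 default_group_params("NT")$mean)
        trials <- generate_trials(make_design(16L), seed = seed)
        res <- sweep_parameter("CostEvidence", base, opts$parameter, grid,
                               trials, seed = seed)
        utils::write.csv(res, out, row.names = FALSE)
      },
      sbc = {
        n <- as.integer(opts$n %||% 50L)
        res <- run_sbc_toy(N = n, seed = seed)
        jsonlite::write_json(
          list(manifest = run_manifest("sbc", list(N = n, seed = seed)),
               uniformity = uniformity_check(res$ranks$mu, res$D)),
          out, auto_unbox = TRUE, digits = NA)
      }
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
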