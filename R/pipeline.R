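# End-to-end orchestration: (simulate or load) -> validate -> preprocess ->
# stable-trial MO2 -> TPC fit -> ramp budgets -> exclusions -> breakpoint
# regression, with seeded stages and a written result bundle.

#' Validate roster, traces and blanks without mutating them
#'
#' Checks every structural invariant: roster consistency
#' ([roster_violations()]), presence and pairing of traces and blanks,
#' strictly increasing time, non-negative DO, and (optionally) design-rate
#' membership.
#'
#' @param roster Roster data frame.
#' @param traces,blanks Named lists of [do_series()] keyed by trial id.
#' @param design_rates_only Flag ramp rates outside the study design set.
#' @return Data frame of violations (`trial_id`, `check`, `message`); zero
#'   rows when everything is valid.
#' @export
validate_inputs <- function(roster, traces, blanks = NULL,
                            design_rates_only = FALSE) {
  out <- roster_violations(roster, design_rates_only = design_rates_only)
  note <- function(id, check, msg)
    out <<- rbind(out, data.frame(trial_id = id, check = check, message = msg,
                                  stringsAsFactors = FALSE))
  for (id in roster$trial_id) {
    tr <- traces[[id]]
    if (is.null(tr)) { note(id, "trace", paste0(id, ": missing trace")); next }
    if (nrow(tr) < 2L) note(id, "trace", paste0(id, ": fewer than 2 samples"))
    if (any(diff(tr$time_min) <= 0)) note(id, "trace", paste0(id, ": non-monotone time"))
    if (any(tr$do_mg_l < 0)) note(id, "trace", paste0(id, ": negative DO"))
    if (!is.null(blanks) && is.null(blanks[[id]]))
      note(id, "blank", paste0(id, ": missing paired blank"))
  }
  out
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or load) the experiment; preprocess every animal trace
#' (blank-slope correction, hypoxia truncation); estimate stable-trial MO2;
#' fit the thermal performance curve; build ramping-trial oxygen budgets;
#' apply exclusions; fit the breakpoint regression; compute stable-trial
#' overlay residuals. The single `seed` fans out to per-stage seeds
#' (`seed + stage index`) so each stage is independently reproducible, and
#' the result bundle is byte-identical across runs with the same
#' configuration.
#'
#' @param config A list. Either `simulate = TRUE` with optional `sim`
#'   (arguments to [sim_config()]; `seed` is managed by the pipeline),
#'   `stable_reps` and `ramp_reps`, or `input = list(roster, trace_dir,
#'   blank_dir)` naming a roster CSV and directories of `<trial_id>.csv`
#'   traces. Further elements (with defaults): `seed` (1),
#'   `hypoxia_threshold` (3), `exponent` (0.8), `log_base` (exp(1)),
#'   `obs_mode` ("multiply"), `exclusion_list` (NULL), `tpc` (list of
#'   [fit_tpc()] settings), `breakpoint` (list of [fit_breakpoint()]
#'   settings), `outdir` (NULL: nothing written).
#' @return A list of class `thermoramp_run`: `roster`, `mo2_table`,
#'   `tpc_fit`, `budgets`, `posterior`, `stable_overlay`,
#'   `exclusion_report`, `validation`, `counts_log`, `config`.
#' @export
run_full_analysis <- function(config = list()) {
  cfg <- utils::modifyList(
    list(simulate = FALSE, sim = list(), stable_reps = 8L, ramp_reps = 4L,
         input = NULL, seed = 1L, hypoxia_threshold = 3, exponent = 0.8,
         log_base = exp(1), obs_mode = "multiply", exclusion_list = NULL,
         tpc = list(), breakpoint = list(), outdir = NULL),
    config)
  seed <- as.integer(cfg$seed)

  # stage 1: inputs
  if (isTRUE(cfg$simulate)) {
    sc <- do.call(sim_config, utils::modifyList(cfg$sim, list(seed = seed + 1L)))
    ex <- simulate_experiment(sc, stable_reps = cfg$stable_reps,
                              ramp_reps = cfg$ramp_reps)
  } else {
    if (is.null(cfg$input))
      stop("run_full_analysis: supply simulate = TRUE or an input list", call. = FALSE)
    roster <- read_roster(cfg$input$roster)
    load_dir <- function(dir) {
      tr <- list()
      for (id in roster$trial_id) {
        p <- file.path(dir, paste0(id, ".csv"))
        if (file.exists(p)) tr[[id]] <- read_do_series(p, trial_id = id)
      }
      tr
    }
    ex <- list(roster = roster, traces = load_dir(cfg$input$trace_dir),
               blanks = load_dir(cfg$input$blank_dir))
  }
  validation <- validate_inputs(ex$roster, ex$traces, ex$blanks)

  # stage 2: preprocess (abort naming the trial if its blank is missing)
  processed <- list()
  for (id in ex$roster$trial_id) {
    tr <- ex$traces[[id]]
    if (is.null(tr))
      stop("preprocess: missing trace for trial ", id, call. = FALSE)
    bl <- ex$blanks[[id]]
    if (is.null(bl))
      stop("preprocess: missing blank for trial ", id, call. = FALSE)
    corrected <- correct_background(tr, fit_blank_slope(bl))
    processed[[id]] <- truncate_hypoxia(corrected, cfg$hypoxia_threshold)
  }

  # stage 3: stable-trial MO2
  mo2_table <- estimate_mo2_table(ex$roster, processed, exponent = cfg$exponent)

  # stage 4: TPC fit on stable trials
  tpc_args <- utils::modifyList(list(seed = seed + 4L), cfg$tpc)
  fit <- do.call(fit_tpc, c(list(mo2_table), tpc_args))

  # stage 5: ramping budgets + exclusions
  budgets <- build_budgets(ex$roster, processed, fit, exponent = cfg$exponent,
                           log_base = cfg$log_base, mode = cfg$obs_mode)
  excl <- apply_exclusions(ex$roster, cfg$exclusion_list, budgets)
  keep <- budgets$trial_id %in% excl$roster$trial_id & !budgets$excluded
  budgets_used <- budgets[keep, , drop = FALSE]

  # stage 6: breakpoint regression + stable overlay
  bp_args <- utils::modifyList(list(seed = seed + 6L), cfg$breakpoint)
  posterior <- do.call(fit_breakpoint, c(list(budgets_used), bp_args))
  overlay <- overlay_stable_residuals(mo2_table, fit, log_base = cfg$log_base)

  counts_log <- data.frame(
    stage = c("measured", "analysed", "budgets_used"),
    heating = c(sum(ex$roster$direction == "heating"),
                excl$counts$analysed[excl$counts$direction == "heating"],
                sum(budgets_used$direction == "heating")),
    cooling = c(sum(ex$roster$direction == "cooling"),
                excl$counts$analysed[excl$counts$direction == "cooling"],
                sum(budgets_used$direction == "cooling")),
    stable = c(sum(ex$roster$direction == "stable"),
               excl$counts$analysed[excl$counts$direction == "stable"], NA))

  result <- structure(
    list(roster = ex$roster, mo2_table = mo2_table, tpc_fit = fit,
         budgets = budgets, budgets_used = budgets_used,
         posterior = posterior, stable_overlay = overlay,
         exclusion_report = excl[c("removals", "counts")],
         validation = validation, counts_log = counts_log, config = cfg),
    class = "thermoramp_run")
  if (!is.null(cfg$outdir)) write_run_bundle(result, cfg$outdir)
  result
}

#' @export
print.thermoramp_run <- function(x, ...) {
  cat("<thermoramp_run>\n")
  print(x$counts_log)
  print(x$tpc_fit)
  print(x$posterior)
  invisible(x)
}

#' Write a pipeline result bundle to disk
#'
#' Emits `mo2_table.csv`, `tpc_fit.json`, `budgets.csv`,
#' `breakpoint_posterior.json`, `draws.csv`, `exclusion_report.json` and a
#' `manifest.json` recording the configuration, seed and package version.
#'
#' @param result A `thermoramp_run` from [run_full_analysis()].
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_run_bundle <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(outdir, f), row.names = FALSE)
  w(result$mo2_table, "mo2_table.csv")
  w(result$budgets, "budgets.csv")
  w(result$posterior$draws, "draws.csv")
  fit <- result$tpc_fit
  jsonlite::write_json(
    list(model_name = fit$model_name, params = as.list(fit$par),
         rss = fit$rss, n = fit$n, k = fit$k, aicc = fit$aicc,
         convergence = fit$convergence),
    file.path(outdir, "tpc_fit.json"), auto_unbox = TRUE, digits = NA)
  post <- result$posterior
  jsonlite::write_json(
    list(summary = post$summary, p_heat_pos = post$p_heat_pos,
         p_cool_neg = post$p_cool_neg, converged = post$converged,
         n_heat = post$n_heat, n_cool = post$n_cool,
         n_chains = post$n_chains, n_iter = post$n_iter,
         n_warmup = post$n_warmup, seed = post$seed, priors = post$priors),
    file.path(outdir, "breakpoint_posterior.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$exclusion_report,
                       file.path(outdir, "exclusion_report.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- result$config
  cfg$log_base <- as.numeric(cfg$log_base)
  cfg$outdir <- NULL   # bundle contents must not depend on where they live
  jsonlite::write_json(
    list(config = cfg, seed = cfg$seed,
         package_version = as.character(utils::packageVersion("thermoramp")),
         r_version = paste(R.version$major, R.version$minor, sep = ".")),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
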