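# Forward simulation of closed-chamber respirometry under the study design:
# 5 stable acclimation temperatures (10, 12, 15, 18, 21 C), 4 ramp regimes
# (15->21, 10->21, 15->10, 21->10 C) x 4 ramp rates (0.5, 1, 5, 10 C/hr),
# 200-ml chambers, wet masses 0.048-0.295 g, paired blank chambers, probe
# sampling 0.2/0.5/1/1 samples per minute by rate.

#' Simulation configuration
#'
#' Ground truth and nuisance settings for the respirometry simulator. The
#' instantaneous DO slope in a chamber holding an animal is
#' \deqn{dDO/dt = -pf(T(t))\, s_i\, e^{\eta \lambda}\, m^{0.8} / V_{eff} + b,}
#' where `pf` is the thermal performance curve evaluated at the (linearly
#' ramped or constant) water temperature, `s_i` a lognormal individual
#' scaling factor, \eqn{e^{\eta \lambda}} an injectable multiplicative
#' ramp-rate effect (so that log residuals are linear in the signed ramp
#' rate \eqn{\lambda}), `m` the wet mass, and `b` the bacterial background
#' drift shared with the paired blank chamber.
#'
#' @param tpc True [tpc_params()] generating metabolic rates.
#' @param noise_sd Gaussian DO observation noise, mg l^-1.
#' @param blank_slope Background (bacterial) drift, mg l^-1 min^-1 (<= 0).
#' @param rate_effect_heat,rate_effect_cool Dimensionless coefficients
#'   \eqn{\eta_h, \eta_c} applied as `exp(eta * lambda)` to consumption for
#'   heating (`lambda > 0`) and cooling (`lambda < 0`) trials; 0 disables
#'   the effect (units: min per degree C).
#' @param individual_sd Standard deviation, on the log scale, of the
#'   per-animal metabolic scaling factor (between-individual variation).
#' @param mass_range_kg Wet-mass range (min, max), kg.
#' @param chamber_volume_l Chamber volume, litres.
#' @param do_start_mg_l DO concentration at sealing, mg l^-1; must exceed
#'   the 3 mg l^-1 hypoxia threshold. The default `NULL` uses air-saturated
#'   water at the trial's starting temperature ([o2_saturation()]),
#'   emulating chambers filled from aerated acclimation tanks.
#' @param stable_duration_min Duration of stable-temperature trials, min.
#' @param step_min Internal forward-integration step, min.
#' @param seed Integer base seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(tpc = tpc_params(0.26, 3.03, 17.93, 0.05),
                       noise_sd = 0.02, blank_slope = -5e-4,
                       rate_effect_heat = 0, rate_effect_cool = 0,
                       individual_sd = 0.15,
                       mass_range_kg = c(4.8e-5, 2.95e-4),
                       chamber_volume_l = 0.2, do_start_mg_l = NULL,
                       stable_duration_min = 90, step_min = 0.1,
                       seed = 1L) {
  stopifnot(inherits(tpc, "tpc_params"), noise_sd >= 0, blank_slope <= 0,
            individual_sd >= 0, step_min > 0, stable_duration_min > 0)
  if (!is.null(do_start_mg_l) && !(do_start_mg_l > 3))
    stop("sim_config: starting DO must exceed the 3 mg/l hypoxia threshold",
         call. = FALSE)
  if (!(mass_range_kg[1] > 0 && mass_range_kg[2] < chamber_volume_l))
    stop("sim_config: mass range must lie within (0, chamber volume)", call. = FALSE)
  structure(list(tpc = tpc, noise_sd = noise_sd, blank_slope = blank_slope,
                 rate_effect_heat = rate_effect_heat,
                 rate_effect_cool = rate_effect_cool,
                 individual_sd = individual_sd,
                 mass_range_kg = mass_range_kg,
                 chamber_volume_l = chamber_volume_l,
                 do_start_mg_l = do_start_mg_l,
                 stable_duration_min = stable_duration_min,
                 step_min = step_min, seed = as.integer(seed)),
            class = "sim_config")
}

#' Oxygen saturation concentration of fresh water
#'
#' Benson-Krause fit for air-saturated fresh water at 1 atm (as tabulated in
#' standard water-quality references); salinity at the fraction of a permille
#' used in brackish acclimation tanks shifts this by well under 1% and is
#' neglected.
#'
#' @param temp_c Water temperature, degrees C (vectorised).
#' @return Dissolved O2 at 100% air saturation, mg l^-1.
#' @export
#' @examples
#' o2_saturation(c(10, 21))  # about 11.3 and 8.9 mg/l
o2_saturation <- function(temp_c) {
  tk <- temp_c + 273.15
  exp(-139.34411 + 1.575701e5 / tk - 6.642308e7 / tk^2 +
        1.2438e10 / tk^3 - 8.621949e11 / tk^4)
}

#' Probe sampling rate used at a given ramp rate
#'
#' The probes recorded at 0.2, 0.5, 1 and 1 samples per minute at ramp rates
#' of 0.5, 1, 5 and 10 C/hr respectively; stable trials use 1 sample per
#' minute.
#'
#' @param lambda_c_per_min Signed ramp rate, degrees C min^-1.
#' @return Samples per minute.
#' @export
sampling_rate_for <- function(lambda_c_per_min) {
  al <- abs(lambda_c_per_min)
  if (al < 1e-9) return(1)
  i <- which(abs(al - design_rates_min) < 1e-6)
  if (length(i) == 1L) design_sampling[i] else 1
}

cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

#' Simulate one chamber trace
#'
#' Integrates the instantaneous DO slope (see [sim_config()]) on a fine
#' fixed grid, subsamples at the probe frequency for the trial's ramp rate,
#' and adds independent Gaussian observation noise. Ramp duration is
#' `|t_end - t_start| / |lambda|`; stable trials run for
#' `config$stable_duration_min`. If DO would reach zero before the end the
#' trace is truncated and flagged (attribute `"clipped"`) with a warning.
#'
#' @param meta One-row roster record ([trial_meta()]).
#' @param config A [sim_config()].
#' @param seed Seed for this trial; defaults to `config$seed`. Identical
#'   seeds give identical traces.
#' @param individual_effect Multiplicative metabolic scaling for this
#'   animal; if `NULL`, drawn lognormal with sd `config$individual_sd`.
#' @return A [do_series()]; attribute `"individual_effect"` records the
#'   scaling used, attribute `"clipped"` whether anoxia truncation occurred.
#' @export
simulate_trial <- function(meta, config, seed = config$seed,
                           individual_effect = NULL) {
  stopifnot(inherits(config, "sim_config"), nrow(meta) == 1L)
  set.seed(seed)
  lambda <- meta$lambda_c_per_min
  dur <- if (abs(lambda) > 0) abs(meta$t_end_c - meta$t_start_c) / abs(lambda)
         else config$stable_duration_min
  if (is.null(individual_effect))
    individual_effect <- exp(stats::rnorm(1, 0, config$individual_sd))
  eta <- if (lambda > 0) config$rate_effect_heat
         else if (lambda < 0) config$rate_effect_cool else 0
  v_eff <- effective_volume(meta$chamber_volume_l, meta$mass_kg)
  do0 <- if (is.null(config$do_start_mg_l)) o2_saturation(meta$t_start_c)
         else config$do_start_mg_l

  tt <- seq(0, dur, by = config$step_min)
  if (tt[length(tt)] < dur) tt <- c(tt, dur)
  temp <- meta$t_start_c + lambda * tt
  rate <- -rezende_pf(temp, config$tpc) * individual_effect *
    exp(eta * lambda) * meta$mass_kg^0.8 / v_eff + config$blank_slope
  do_fine <- do0 + cumtrapz(tt, rate)

  clipped <- FALSE
  if (any(do_fine <= 0)) {
    cut <- which(do_fine <= 0)[1L] - 1L
    if (cut < 2L) stop("simulate_trial: DO depleted immediately", call. = FALSE)
    tt <- tt[seq_len(cut)]; temp <- temp[seq_len(cut)]; do_fine <- do_fine[seq_len(cut)]
    clipped <- TRUE
    warning(sprintf("trial %s: DO reached zero; trace truncated at %.1f min",
                    meta$trial_id, tt[length(tt)]), call. = FALSE)
  }

  sr <- sampling_rate_for(lambda)
  ts <- seq(0, tt[length(tt)], by = 1 / sr)
  do_obs <- stats::approx(tt, do_fine, xout = ts)$y +
    stats::rnorm(length(ts), 0, config$noise_sd)
  do_obs <- pmax(do_obs, 0)
  temp_obs <- meta$t_start_c + lambda * ts
  out <- do_series(ts, do_obs, temp_obs, trial_id = meta$trial_id,
                   sampling_rate = sr)
  attr(out, "individual_effect") <- individual_effect
  attr(out, "clipped") <- clipped
  out
}

#' Simulate a blank (control) chamber
#'
#' Blanks contain tank water but no animal, so DO declines only at the
#' bacterial background slope (plus observation noise).
#'
#' @param duration_min Trace duration, min (> 0).
#' @param config A [sim_config()].
#' @param sampling_rate Samples per minute.
#' @param seed Seed; identical seeds give identical traces.
#' @param trial_id Label of the paired animal trial.
#' @param t_start_c Bath temperature at sealing; sets the saturation
#'   starting DO when `config$do_start_mg_l` is `NULL`.
#' @return A [do_series()].
#' @export
simulate_blank <- function(duration_min, config, sampling_rate = 1,
                           seed = config$seed, trial_id = NA_character_,
                           t_start_c = 15) {
  stopifnot(duration_min > 0)
  set.seed(seed)
  do0 <- if (is.null(config$do_start_mg_l)) o2_saturation(t_start_c)
         else config$do_start_mg_l
  ts <- seq(0, duration_min, by = 1 / sampling_rate)
  do_obs <- do0 + config$blank_slope * ts +
    stats::rnorm(length(ts), 0, config$noise_sd)
  do_series(ts, pmax(do_obs, 0), rep(NA_real_, length(ts)),
            trial_id = trial_id, sampling_rate = sampling_rate)
}

#' Simulate a full experiment
#'
#' Emits trials covering the whole design: every stable acclimation
#' temperature (10, 12, 15, 18, 21 C) and every ramp regime (15->21, 10->21,
#' 15->10, 21->10 C) at every ramp rate (0.5, 1, 5, 10 C/hr), with wet
#' masses drawn uniformly from the configured range and one paired blank per
#' trial. With one replicate everywhere this yields 5 + 16 = 21 trials.
#'
#' @param config A [sim_config()].
#' @param stable_reps Replicates per stable temperature: a scalar or a
#'   length-5 vector (order 10, 12, 15, 18, 21 C).
#' @param ramp_reps Replicates per ramp cell: a scalar or a length-16 vector
#'   (cells ordered regime-major: 15->21, 10->21, 15->10, 21->10, each at
#'   0.5, 1, 5, 10 C/hr).
#' @return A list with `roster` (data frame), `traces` and `blanks` (lists
#'   of [do_series()] keyed by trial id).
#' @export
#' @examples
#' ex <- simulate_experiment(sim_config(seed = 42))
#' nrow(ex$roster)  # 21
simulate_experiment <- function(config, stable_reps = 1L, ramp_reps = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (length(stable_reps) == 1L) stable_reps <- rep(stable_reps, 5L)
  stopifnot(length(stable_reps) == 5L)
  regimes <- data.frame(t_start = c(15, 10, 15, 21), t_end = c(21, 21, 10, 10))
  cells <- merge(data.frame(regime = 1:4), data.frame(rate = 1:4))
  cells <- cells[order(cells$regime, cells$rate), ]
  if (length(ramp_reps) == 1L) ramp_reps <- rep(ramp_reps, 16L)
  stopifnot(length(ramp_reps) == 16L)

  rate_label <- c("0.5", "1", "5", "10")
  rows <- list()
  animal <- 0L
  for (j in seq_len(5L)) {
    tt <- design_stable_temps[j]
    for (r in seq_len(stable_reps[j])) {
      animal <- animal + 1L
      rows[[length(rows) + 1L]] <-
        list(id = sprintf("%dT%02d%02dR0", animal, tt, tt),
             t_start = tt, t_end = tt, lambda = 0, direction = "stable")
    }
  }
  for (ci in seq_len(16L)) {
    rg <- regimes[cells$regime[ci], ]
    lam <- design_rates_min[cells$rate[ci]] * sign(rg$t_end - rg$t_start)
    for (r in seq_len(ramp_reps[ci])) {
      animal <- animal + 1L
      rows[[length(rows) + 1L]] <-
        list(id = sprintf("%dT%02d%02dR%s", animal, rg$t_start, rg$t_end,
                          rate_label[cells$rate[ci]]),
             t_start = rg$t_start, t_end = rg$t_end, lambda = lam,
             direction = if (lam > 0) "heating" else "cooling")
    }
  }

  set.seed(config$seed)
  n <- length(rows)
  masses <- stats::runif(n, config$mass_range_kg[1], config$mass_range_kg[2])
  trial_seeds <- config$seed + seq_len(n)
  blank_seeds <- config$seed + 100000L + seq_len(n)

  roster <- do.call(rbind, lapply(seq_len(n), function(i) {
    r <- rows[[i]]
    trial_meta(r$id, i, r$direction, r$t_start, r$t_end, r$lambda,
               masses[i], config$chamber_volume_l, acclim_temp_c = r$t_start)
  }))
  traces <- list(); blanks <- list()
  for (i in seq_len(n)) {
    meta <- roster[i, ]
    tr <- simulate_trial(meta, config, seed = trial_seeds[i])
    traces[[meta$trial_id]] <- tr
    blanks[[meta$trial_id]] <-
      simulate_blank(max(tr$time_min), config,
                     sampling_rate = sampling_rate(tr),
                     seed = blank_seeds[i], trial_id = meta$trial_id,
                     t_start_c = meta$t_start_c)
  }
  list(roster = roster, traces = traces, blanks = blanks)
}
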