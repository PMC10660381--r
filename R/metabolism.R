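#' Effective chamber volume
#'
#' The water volume available for oxygen depletion: chamber volume minus the
#' animal's volume, approximated by its mass at density 1 (neutral
#' buoyancy), so litres minus kilograms.
#'
#' @param chamber_volume_l Chamber volume, litres.
#' @param mass_kg Animal wet mass, kg; must be positive and below the
#'   chamber volume.
#' @return Effective volume, litres.
#' @export
#' @examples
#' effective_volume(0.2, 0.0001)  # 0.1999 l
effective_volume <- function(chamber_volume_l, mass_kg) {
  if (any(mass_kg <= 0))
    stop("effective_volume: mass must be positive", call. = FALSE)
  if (any(mass_kg >= chamber_volume_l))
    stop("effective_volume: mass must be below the chamber volume", call. = FALSE)
  chamber_volume_l - mass_kg
}

#' Estimate mass-scaled metabolic rate from a stable-trial trace
#'
#' Fits an ordinary least-squares line to DO concentration versus time over
#' the whole (corrected, truncated) trace and converts its slope `m`
#' (mg l^-1 min^-1) to a mass-scaled oxygen consumption rate
#' \deqn{MO_2 = -m \; V_{eff} / mass^{0.8}}
#' in mg O2 min^-1 kg^-0.8, reported positive when DO declines. The
#' allometric exponent 0.8 is the conventional value for crustaceans and is
#' exposed for sensitivity analyses. A non-negative DO slope is allowed but
#' flagged.
#'
#' @param series A corrected, truncated [do_series()].
#' @param mass_kg Wet mass, kg.
#' @param chamber_volume_l Chamber volume, litres.
#' @param exponent Allometric mass-scaling exponent.
#' @return One-row data frame with `trial_id`, `mo2`, `mean_temp_c`,
#'   `slope_do`, `v_eff_l` and `flagged` (TRUE when MO2 <= 0).
#' @export
estimate_mo2 <- function(series, mass_kg, chamber_volume_l, exponent = 0.8) {
  stopifnot(nrow(series) >= 2L)
  v_eff <- effective_volume(chamber_volume_l, mass_kg)
  m <- unname(stats::coef(stats::lm(do_mg_l ~ time_min, data = series))[2L])
  mo2 <- -m * v_eff / mass_kg^exponent
  data.frame(trial_id = trial_id(series), mo2 = mo2,
             mean_temp_c = mean(series$temp_c), slope_do = m,
             v_eff_l = v_eff, flagged = mo2 <= 1e-10,
             stringsAsFactors = FALSE)
}

#' MO2 table for the stable trials of a roster
#'
#' Runs [estimate_mo2()] over every stable trial, pulling mass and chamber
#' volume from the roster.
#'
#' @param roster Roster data frame.
#' @param traces Named list of preprocessed [do_series()] keyed by trial id.
#' @param exponent Allometric mass-scaling exponent.
#' @return Data frame with one row per stable trial.
#' @export
estimate_mo2_table <- function(roster, traces, exponent = 0.8) {
  stable <- roster[roster$direction == "stable", , drop = FALSE]
  rows <- lapply(seq_len(nrow(stable)), function(i) {
    r <- stable[i, ]
    tr <- traces[[r$trial_id]]
    if (is.null(tr)) stop("missing trace for trial ", r$trial_id, call. = FALSE)
    estimate_mo2(tr, r$mass_kg, r$chamber_volume_l, exponent)
  })
  do.call(rbind, rows)
}

#' Observed total oxygen consumption of a trial
#'
#' The concentration drop is taken as the mean of the first five DO samples
#' minus the mean of the last five. The default mode converts it to a mass
#' of oxygen by multiplying by the effective volume
#' (mg l^-1 x l = mg). Mode `"divide"` instead divides the drop by the
#' effective volume; it is retained purely for auditability of the
#' alternative convention and is not dimensionally a mass.
#'
#' @param series A corrected [do_series()] with at least 10 samples.
#' @param v_eff_l Effective volume, litres.
#' @param mode `"multiply"` (default) or `"divide"`.
#' @return Total O2 consumed, mg (in the default mode).
#' @export
observed_total_o2 <- function(series, v_eff_l, mode = c("multiply", "divide")) {
  mode <- match.arg(mode)
  if (nrow(series) < 10L)
    stop("observed_total_o2: need at least 10 samples", call. = FALSE)
  dc <- mean(utils::head(series$do_mg_l, 5L)) - mean(utils::tail(series$do_mg_l, 5L))
  if (mode == "multiply") dc * v_eff_l else dc / v_eff_l
}
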