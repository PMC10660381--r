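# Integral prediction of total O2 consumption over a temperature ramp, and
# log residuals of observed against predicted consumption.

#' Integrate a thermal performance curve between two temperatures
#'
#' Signed adaptive quadrature of the performance curve:
#' \eqn{\int_{t_1}^{t_2} pf(T)\,dT}. The integration domain is split at the
#' threshold temperature, where the integrand has a derivative
#' discontinuity, so each piece is smooth.
#'
#' @param params A [tpc_params()] object or a fitted `tpc_fit` (its
#'   parameters are used).
#' @param t1_c,t2_c Integration bounds, degrees C, in either order; the
#'   result is antisymmetric in the bounds.
#' @param tol Absolute error tolerance.
#' @return The signed integral, rate x degrees C units.
#' @export
#' @examples
#' p <- tpc_params(0.26, 3.03, 17.93, 0.05)
#' integrate_tpc(p, 10, 15)
integrate_tpc <- function(params, t1_c, t2_c, tol = 1e-8) {
  if (inherits(params, "tpc_fit")) params <- params$params
  stopifnot(inherits(params, "tpc_params"))
  if (t1_c == t2_c) return(0)
  s <- if (t2_c >= t1_c) 1 else -1
  lo <- min(t1_c, t2_c); hi <- max(t1_c, t2_c)
  cuts <- unique(c(lo, if (params$t_th > lo && params$t_th < hi) params$t_th, hi))
  total <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    piece <- stats::integrate(function(t) rezende_pf(t, params),
                              cuts[i], cuts[i + 1L],
                              rel.tol = .Machine$double.eps^0.5,
                              abs.tol = tol, subdivisions = 500L)
    total <- total + piece$value
  }
  s * total
}

#' Predicted total oxygen consumption of a ramping trial
#'
#' Converts the TPC integral between the trial's start and end temperatures
#' into a mass of oxygen by dividing by the (signed) ramp rate — which turns
#' degrees C into minutes of exposure — and multiplying by the allometric
#' mass term:
#' \deqn{\mathrm{predicted} = \frac{\int pf\,dT}{\lambda}\, mass^{0.8}.}
#' With the signed conventions the result is positive for both heating and
#' cooling (integral and rate share sign).
#'
#' @param integral Signed TPC integral from [integrate_tpc()], taken from
#'   start to end temperature.
#' @param lambda_c_per_min Signed ramp rate, degrees C min^-1; must be
#'   non-zero.
#' @param mass_kg Wet mass, kg.
#' @param exponent Allometric mass-scaling exponent.
#' @return Predicted total O2 consumption, mg.
#' @export
predicted_total_o2 <- function(integral, lambda_c_per_min, mass_kg,
                               exponent = 0.8) {
  if (lambda_c_per_min == 0)
    stop("predicted_total_o2: lambda is zero; stable trials are predicted as pf(T) * duration * mass^exponent",
         call. = FALSE)
  integral / lambda_c_per_min * mass_kg^exponent
}

#' Log residual of observed against predicted consumption
#'
#' `log(observed) - log(predicted)` in the configured base (natural log by
#' default). Defined only for positive observed and predicted values;
#' non-positive inputs yield `NA`, which downstream exclusion handling turns
#' into a recorded removal.
#'
#' @param observed_mg,predicted_mg Total O2 consumption, mg (vectorised).
#' @param log_base Logarithm base.
#' @return Residual(s) in log units (`NA` where undefined).
#' @export
compute_residual <- function(observed_mg, predicted_mg, log_base = exp(1)) {
  ok <- is.finite(observed_mg) & is.finite(predicted_mg) &
    observed_mg > 0 & predicted_mg > 0
  out <- rep(NA_real_, length(ok))
  out[ok] <- (log(observed_mg[ok]) - log(predicted_mg[ok])) / log(log_base)
  out
}

#' Oxygen budgets for all ramping trials
#'
#' For every heating or cooling trial in the roster: the observed total O2
#' consumption from its (preprocessed) trace, the TPC-integral prediction
#' between its start and end temperatures, and the log residual. Trials
#' whose residual is undefined (non-positive observed or predicted
#' consumption) or whose trace is unusable are flagged excluded with a
#' reason instead of aborting the batch. Stable trials never appear.
#'
#' @param roster Roster data frame.
#' @param traces Named list of preprocessed [do_series()] keyed by trial id.
#' @param fit A `tpc_fit` (fitted on stable trials) or [tpc_params()].
#' @param exponent Allometric mass-scaling exponent.
#' @param log_base Logarithm base for residuals.
#' @param mode Observed-consumption volume convention, see
#'   [observed_total_o2()].
#' @return Data frame with columns `trial_id`, `direction`,
#'   `lambda_c_per_min`, `observed_mg`, `predicted_mg`, `residual`,
#'   `excluded`, `reason`.
#' @export
build_budgets <- function(roster, traces, fit, exponent = 0.8,
                          log_base = exp(1), mode = "multiply") {
  params <- if (inherits(fit, "tpc_fit")) fit$params else fit
  ramping <- roster[roster$direction != "stable", , drop = FALSE]
  rows <- lapply(seq_len(nrow(ramping)), function(i) {
    r <- ramping[i, ]
    out <- data.frame(trial_id = r$trial_id, direction = r$direction,
                      lambda_c_per_min = r$lambda_c_per_min,
                      observed_mg = NA_real_, predicted_mg = NA_real_,
                      residual = NA_real_, excluded = FALSE, reason = "",
                      stringsAsFactors = FALSE)
    tr <- traces[[r$trial_id]]
    if (is.null(tr)) {
      out$excluded <- TRUE; out$reason <- "missing trace"
      return(out)
    }
    v_eff <- effective_volume(r$chamber_volume_l, r$mass_kg)
    obs <- tryCatch(observed_total_o2(tr, v_eff, mode = mode),
                    error = function(e) NA_real_)
    pred <- predicted_total_o2(integrate_tpc(params, r$t_start_c, r$t_end_c),
                               r$lambda_c_per_min, r$mass_kg, exponent)
    out$observed_mg <- obs
    out$predicted_mg <- pred
    if (!is.finite(obs)) {
      out$excluded <- TRUE; out$reason <- "trace too short for observed consumption"
    } else if (obs <= 0) {
      out$excluded <- TRUE; out$reason <- "non-positive observed O2 consumption"
    } else if (!is.finite(pred) || pred <= 0) {
      out$excluded <- TRUE; out$reason <- "non-positive predicted O2 consumption"
    } else {
      out$residual <- compute_residual(obs, pred, log_base)
    }
    out
  })
  do.call(rbind, rows)
}
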