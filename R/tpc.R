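#' Piecewise-Q10 thermal performance parameters
#'
#' The piecewise-Q10 ("Rezende") thermal performance curve rises
#' exponentially with temperature below a threshold and is damped by a
#' quadratic decay term above it:
#' \deqn{pf(T) = C\,Q_{10}^{T/10} \quad (T \le T_{th}), \qquad
#'       pf(T) = C\,Q_{10}^{T/10}\,[1 - d (T - T_{th})^2] \quad (T > T_{th}).}
#'
#' @param ce Pre-exponential rate constant \eqn{C} (rate units at 0 C).
#' @param q10 Fold change in rate per 10 C increase; must exceed 1.
#' @param t_th Threshold temperature, degrees C, above which decay begins.
#' @param d Decay constant, per squared degree C; non-negative.
#' @return An object of class `tpc_params`.
#' @export
#' @examples
#' p <- tpc_params(ce = 0.26, q10 = 3.03, t_th = 17.93, d = 0.05)
#' rezende_pf(c(10, 17.93, 21), p)
tpc_params <- function(ce, q10, t_th, d) {
  if (!(ce > 0)) stop("tpc_params: ce must be positive", call. = FALSE)
  if (!(q10 > 1)) stop("tpc_params: q10 must exceed 1", call. = FALSE)
  if (!(d >= 0)) stop("tpc_params: d must be non-negative", call. = FALSE)
  structure(list(ce = ce, q10 = q10, t_th = t_th, d = d), class = "tpc_params")
}

#' @export
print.tpc_params <- function(x, ...) {
  cat(sprintf("<tpc_params> ce = %.4g, q10 = %.4g, t_th = %.4g C, d = %.4g\n",
              x$ce, x$q10, x$t_th, x$d))
  invisible(x)
}

#' Evaluate the piecewise-Q10 performance curve
#'
#' Continuous at `t_th` (the decay factor equals 1 there); strictly
#' increasing below `t_th` for `q10 > 1`. The curve can become negative far
#' above `t_th` when `d > 0`; values are returned unclamped.
#'
#' @param t_c Temperatures, degrees C (vectorised).
#' @param params A [tpc_params()] object.
#' @return Performance (metabolic rate) at each temperature.
#' @export
rezende_pf <- function(t_c, params) {
  base <- params$ce * params$q10^(t_c / 10)
  decay <- ifelse(t_c > params$t_th,
                  1 - params$d * (t_c - params$t_th)^2, 1)
  base * decay
}

# vector-parameter form used by the fitting machinery
rezende_pf_vec <- function(t_c, par) {
  rezende_pf(t_c, structure(list(ce = par[1], q10 = par[2],
                                 t_th = par[3], d = par[4]),
                            class = "tpc_params"))
}

#' Small-sample Akaike information criterion
#'
#' Gaussian-likelihood form based on the residual sum of squares:
#' \deqn{AICc = n \ln(RSS/n) + 2k + \frac{2k(k+1)}{n-k-1}.}
#' `k` counts all estimated parameters including the residual variance.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of observations.
#' @param k Number of estimated parameters.
#' @return The AICc score (lower is better).
#' @export
aicc <- function(rss, n, k) {
  if (!(rss > 0)) stop("aicc: rss must be positive", call. = FALSE)
  if (n <= k + 1) stop("aicc: undefined for n <= k + 1", call. = FALSE)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# ---- candidate model registry ----------------------------------------------

.tpc_registry <- new.env(parent = emptyenv())

#' Register or look up a candidate TPC model
#'
#' The fitting and selection machinery is model-agnostic: a candidate is a
#' name, a rate function `fn(t_c, par)` over a numeric parameter vector, the
#' parameter names, and default box bounds (each bound may be a number or a
#' function of the data temperatures). The piecewise-Q10 model is built in;
#' further models can be plugged in without touching the fitting code.
#'
#' @param name Model name.
#' @param fn Function `(t_c, par)` returning rates.
#' @param par_names Character vector of parameter names.
#' @param lower,upper Numeric vectors, or functions of the observed
#'   temperatures returning numeric vectors, giving box bounds per parameter.
#' @param profile Optional function `(t_c, y, par)` returning an improved
#'   parameter vector, used to polish random starts before screening (e.g.
#'   solving conditionally linear parameters by least squares).
#' @return `tpc_model()` returns the registered model record.
#' @export
register_tpc_model <- function(name, fn, par_names, lower, upper,
                               profile = NULL) {
  assign(name, list(name = name, fn = fn, par_names = par_names,
                    lower = lower, upper = upper, profile = profile),
         envir = .tpc_registry)
  invisible(name)
}

#' @rdname register_tpc_model
#' @export
tpc_model <- function(name) {
  if (!exists(name, envir = .tpc_registry))
    stop("unknown TPC model '", name, "'", call. = FALSE)
  get(name, envir = .tpc_registry)
}

#' @rdname register_tpc_model
#' @export
tpc_models <- function() sort(ls(envir = .tpc_registry))

# given (q10, t_th) the curve is linear in (ce, ce*d): solve both by OLS
rezende_profile <- function(t_c, y, par) {
  g <- par[2]^(t_c / 10)
  x2 <- -g * pmax(t_c - par[3], 0)^2
  cf <- tryCatch(stats::lm.fit(cbind(g, x2), y)$coefficients,
                 error = function(e) c(NA_real_, NA_real_))
  if (all(is.finite(cf)) && cf[1] > 0) {
    par[1] <- cf[1]
    par[4] <- max(cf[2] / cf[1], 0)
  }
  par
}

register_tpc_model(
  "rezende", rezende_pf_vec,
  par_names = c("ce", "q10", "t_th", "d"),
  lower = function(t) c(1e-3, 1 + 1e-6, min(t), 0),
  upper = function(t) c(10, 10, max(t) + 5, 1),
  profile = rezende_profile
)

resolve_bound <- function(b, temps) if (is.function(b)) b(temps) else b

# ---- fitting ----------------------------------------------------------------

#' Fit a thermal performance curve by multistart nonlinear least squares
#'
#' Minimises the residual sum of squares of observed rates against the
#' candidate model. `n_starts` parameter vectors are drawn uniformly within
#' the box bounds (seeded, hence reproducible); the `refine` most promising
#' starts (lowest starting RSS) are polished with bounded
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]), and the best converged fit
#' is returned with its AICc. The parameter count for AICc is the number of
#' shape parameters plus one for the residual variance.
#'
#' @param temp_c Temperatures of the rate observations, degrees C. May also
#'   be a data frame with columns `mean_temp_c` and `mo2` (e.g. the output
#'   of [estimate_mo2_table()]), in which case `mo2` is ignored.
#' @param mo2 Observed rates (mass-scaled MO2).
#' @param model Candidate model name (see [tpc_models()]).
#' @param n_starts Number of random starts screened.
#' @param refine Number of best starts polished by Levenberg-Marquardt.
#' @param lower,upper Optional bound overrides.
#' @param seed Integer seed for the random starts.
#' @return An object of class `tpc_fit`: `params` (a [tpc_params()] for the
#'   piecewise-Q10 model, else a named vector), `par`, `rss`, `n`, `k`,
#'   `aicc`, `model_name` and convergence metadata.
#' @export
fit_tpc <- function(temp_c, mo2 = NULL, model = "rezende", n_starts = 250L,
                    refine = 10L, lower = NULL, upper = NULL, seed = 1L) {
  if (is.data.frame(temp_c)) {
    mo2 <- temp_c$mo2
    temp_c <- temp_c$mean_temp_c
  }
  keep <- is.finite(temp_c) & is.finite(mo2)
  temp_c <- temp_c[keep]; mo2 <- mo2[keep]
  ord <- order(temp_c, mo2)   # canonical order: fits are order-invariant
  temp_c <- temp_c[ord]; mo2 <- mo2[ord]
  n <- length(temp_c)
  if (n < 6L) stop("fit_tpc: need at least 6 points", call. = FALSE)
  if (length(unique(round(temp_c, 6))) < 3L)
    stop("fit_tpc: insufficient temperature span (need >= 3 distinct temperatures)",
         call. = FALSE)
  mod <- tpc_model(model)
  lo <- if (is.null(lower)) resolve_bound(mod$lower, temp_c) else lower
  hi <- if (is.null(upper)) resolve_bound(mod$upper, temp_c) else upper
  p <- length(mod$par_names)
  stopifnot(length(lo) == p, length(hi) == p)

  rss_of <- function(par) {
    r <- mo2 - mod$fn(temp_c, par)
    sum(r * r)
  }
  set.seed(seed)
  starts <- matrix(stats::runif(n_starts * p, rep(lo, each = n_starts),
                                rep(hi, each = n_starts)),
                   nrow = n_starts, ncol = p)
  if (!is.null(mod$profile)) {
    for (i in seq_len(n_starts)) {
      pr <- mod$profile(temp_c, mo2, starts[i, ])
      starts[i, ] <- pmin(pmax(pr, lo), hi)
    }
  }
  start_rss <- apply(starts, 1L, rss_of)
  ord <- order(start_rss)[seq_len(min(refine, n_starts))]

  fits <- list()
  for (i in ord) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ],
                         fn = function(par) mo2 - mod$fn(temp_c, par),
                         lower = lo, upper = hi,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
  }
  n_converged <- length(fits)
  best <- NULL
  if (n_converged > 0L) {
    devs <- vapply(fits, function(f) f$deviance, numeric(1))
    # the least-squares surface can be ridge-degenerate (e.g. threshold and
    # decay trading off when few temperatures exceed the threshold); among
    # RSS ties take the minimum-norm parameter vector, a deterministic
    # convention that prefers interior, least-decay solutions
    tied <- which(devs <= min(devs) * (1 + 1e-9) + 1e-12)
    norms <- vapply(fits[tied], function(f) sum(as.numeric(f$par)^2), numeric(1))
    best <- fits[[tied[which.min(norms)]]]
  }
  if (is.null(best))
    stop(sprintf("fit_tpc: no start converged (%d starts screened, %d polished)",
                 n_starts, length(ord)), call. = FALSE)

  par <- stats::setNames(as.numeric(best$par), mod$par_names)
  k <- p + 1L
  rss <- best$deviance
  params <- if (model == "rezende")
    tpc_params(par[["ce"]], par[["q10"]], par[["t_th"]], par[["d"]]) else par
  structure(list(params = params, par = par, rss = rss, n = n, k = k,
                 aicc = aicc(rss, n, k), model_name = model,
                 convergence = list(n_starts = n_starts, refine = length(ord),
                                    n_converged = n_converged, seed = seed)),
            class = "tpc_fit")
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat(sprintf("<tpc_fit> model '%s': n = %d, k = %d, RSS = %.4g, AICc = %.3f\n",
              x$model_name, x$n, x$k, x$rss, x$aicc))
  print(round(x$par, 4))
  invisible(x)
}

#' @export
predict.tpc_fit <- function(object, newdata, ...) {
  t_c <- if (is.data.frame(newdata)) newdata$mean_temp_c else newdata
  tpc_model(object$model_name)$fn(t_c, object$par)
}

#' Select the best candidate fit by AICc
#'
#' Returns the fit with the lowest AICc; ties are broken by fewer
#' parameters, then alphabetically by model name.
#'
#' @param fits List of `tpc_fit` objects.
#' @return The selected `tpc_fit`.
#' @export
select_model <- function(fits) {
  if (length(fits) == 0L) stop("select_model: empty fit list", call. = FALSE)
  score <- vapply(fits, function(f) f$aicc, numeric(1))
  kk <- vapply(fits, function(f) f$k, numeric(1))
  nm <- vapply(fits, function(f) f$model_name, character(1))
  fits[[order(score, kk, nm)[1L]]]
}
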