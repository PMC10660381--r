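# Bayesian piecewise-linear ("breakpoint") regression of log residuals on
# signed ramp rate, with the breakpoint fixed at lambda = 0 so heating and
# cooling get separate slopes around a shared intercept.

#' Fit the breakpoint-at-zero regression of residuals on ramp rate
#'
#' Model, for log residual \eqn{y_i} and signed ramp rate \eqn{\lambda_i}:
#' \deqn{y_i = a + b_{heat}\,\lambda_i\,1[\lambda_i > 0]
#'            + b_{cool}\,\lambda_i\,1[\lambda_i < 0] + \epsilon_i,\quad
#'       \epsilon_i \sim N(0, \sigma^2),}
#' continuous at \eqn{\lambda = 0} by construction (shared intercept `a`).
#' Priors: independent Normal(0, `coef_sd`) on `a`, `b_heat`, `b_cool` and
#' Half-Normal(`sigma_sd`) on `sigma` — weakly informative at this study's
#' scale. The posterior is sampled by Gibbs updates of the coefficient
#' block (conditionally Gaussian) alternated with slice-sampling of
#' `log(sigma)`; chains are seeded so results are reproducible.
#'
#' Convergence is gated on split-Rhat <= 1.01 and effective sample size
#' >= 400 per parameter; failures set `converged = FALSE` with a warning
#' rather than being silently returned.
#'
#' @param budgets Budget table from [build_budgets()] (rows with
#'   `excluded = TRUE` or undefined residuals are dropped), or any data
#'   frame with columns `residual` and `lambda_c_per_min`.
#' @param priors List with `coef_sd` and `sigma_sd`.
#' @param n_chains,n_iter,n_warmup Sampler size; draws kept =
#'   `n_chains * (n_iter - n_warmup)`.
#' @param seed Integer seed.
#' @return An object of class `breakpoint_posterior`: `draws` (data frame
#'   with columns `a`, `b_heat`, `b_cool`, `sigma`), `summary` (means, sds,
#'   95% credible intervals), `p_heat_pos` = P(b_heat > 0), `p_cool_neg` =
#'   P(b_cool < 0), `rhat`, `ess`, `converged`, and the sampler settings.
#' @export
fit_breakpoint <- function(budgets,
                           priors = list(coef_sd = 100, sigma_sd = 10),
                           n_chains = 4L, n_iter = 2000L, n_warmup = 1000L,
                           seed = 1L) {
  stopifnot(n_iter > n_warmup, n_warmup >= 0L, n_chains >= 1L)
  keep <- is.finite(budgets$residual) & budgets$lambda_c_per_min != 0
  if ("excluded" %in% names(budgets)) keep <- keep & !budgets$excluded
  y <- budgets$residual[keep]
  lam <- budgets$lambda_c_per_min[keep]
  if (sum(lam > 0) < 3L || sum(lam < 0) < 3L)
    stop("fit_breakpoint: need at least 3 heating and 3 cooling residuals",
         call. = FALSE)
  X <- cbind(a = 1, b_heat = lam * (lam > 0), b_cool = lam * (lam < 0))
  n <- length(y)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  prior_prec <- diag(1 / priors$coef_sd^2, 3L)

  ols <- stats::lm.fit(X, y)
  sigma0 <- max(sqrt(sum(ols$residuals^2) / max(n - 3L, 1L)), 1e-3)

  n_keep <- n_iter - n_warmup
  draws_arr <- array(NA_real_, dim = c(n_keep, n_chains, 4L),
                     dimnames = list(NULL, NULL, c("a", "b_heat", "b_cool", "sigma")))
  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch)
    beta <- ols$coefficients + stats::rnorm(3L, 0, 0.1 * sigma0 + 1e-6)
    u <- log(sigma0 * exp(stats::rnorm(1, 0, 0.2)))
    for (it in seq_len(n_iter)) {
      # coefficients | sigma: Gaussian
      sig2 <- exp(2 * u)
      prec <- XtX / sig2 + prior_prec
      ch_u <- chol(prec)
      mu <- backsolve(ch_u, forwardsolve(t(ch_u), Xty / sig2))
      beta <- drop(mu + backsolve(ch_u, stats::rnorm(3L)))
      # log(sigma) | coefficients: slice
      rss <- sum((y - X %*% beta)^2)
      # support bounded to keep exp(2v) inside floating-point range; the
      # lower bound also regularises the degenerate all-zero-residual case
      logf <- function(v) {
        if (v < -20 || v > 20) return(-Inf)
        -n * v - rss / (2 * exp(2 * v)) - exp(2 * v) / (2 * priors$sigma_sd^2) + v
      }
      u <- slice_sample1(u, logf, w = 0.5)
      if (it > n_warmup)
        draws_arr[it - n_warmup, ch, ] <- c(beta, exp(u))
    }
  }

  pars <- c("a", "b_heat", "b_cool", "sigma")
  rhat <- vapply(pars, function(p) split_rhat(draws_arr[, , p, drop = TRUE]),
                 numeric(1))
  ess <- vapply(pars, function(p) ess_chains(as.matrix(draws_arr[, , p])),
                numeric(1))
  draws <- as.data.frame(apply(draws_arr, 3L, as.numeric))
  names(draws) <- pars
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  summ <- data.frame(parameter = pars,
                     mean = vapply(draws, mean, numeric(1)),
                     sd = vapply(draws, stats::sd, numeric(1)),
                     q2.5 = vapply(draws, function(x) qs(x)[1], numeric(1)),
                     q97.5 = vapply(draws, function(x) qs(x)[2], numeric(1)),
                     rhat = unname(rhat), ess = unname(ess),
                     row.names = NULL, stringsAsFactors = FALSE)
  converged <- all(rhat <= 1.01) && all(ess >= 400)
  if (!converged)
    warning("fit_breakpoint: convergence diagnostics failed (max rhat = ",
            round(max(rhat), 4), ", min ess = ", round(min(ess)), ")",
            call. = FALSE)
  structure(list(draws = draws, summary = summ,
                 p_heat_pos = mean(draws$b_heat > 0),
                 p_cool_neg = mean(draws$b_cool < 0),
                 rhat = rhat, ess = ess, converged = converged,
                 n_heat = sum(lam > 0), n_cool = sum(lam < 0),
                 n_chains = n_chains, n_iter = n_iter, n_warmup = n_warmup,
                 seed = seed, priors = priors),
            class = "breakpoint_posterior")
}

#' @export
print.breakpoint_posterior <- function(x, ...) {
  cat(sprintf("<breakpoint_posterior> %d heating + %d cooling residuals, %d draws\n",
              x$n_heat, x$n_cool, nrow(x$draws)))
  print(transform(x$summary, mean = round(mean, 4), sd = round(sd, 4),
                  q2.5 = round(q2.5, 4), q97.5 = round(q97.5, 4),
                  rhat = round(rhat, 3), ess = round(ess)))
  cat(sprintf("P(b_heat > 0) = %.3f   P(b_cool < 0) = %.3f   converged: %s\n",
              x$p_heat_pos, x$p_cool_neg, x$converged))
  invisible(x)
}

#' Posterior probability of a predicate
#'
#' Fraction of post-warmup draws satisfying a predicate, with a Monte Carlo
#' standard error based on the effective sample size of the indicator
#' series.
#'
#' @param draws Numeric vector of posterior draws (>= 1000), or a
#'   `breakpoint_posterior` (supply `parameter`).
#' @param predicate Function mapping draws to logical, e.g.
#'   `function(x) x > 0`.
#' @param parameter Column to use when `draws` is a `breakpoint_posterior`.
#' @return List with `prob` and `mcse`.
#' @export
posterior_prob <- function(draws, predicate, parameter = NULL) {
  if (inherits(draws, "breakpoint_posterior")) {
    stopifnot(!is.null(parameter))
    draws <- draws$draws[[parameter]]
  }
  if (length(draws) < 1000L)
    stop("posterior_prob: need at least 1000 draws", call. = FALSE)
  ind <- as.numeric(predicate(draws))
  p <- mean(ind)
  ess <- ess_geyer_one(ind)
  list(prob = p, mcse = sqrt(max(p * (1 - p), 0) / ess))
}

#' Residuals of stable trials at lambda = 0
#'
#' For a stable trial at temperature T, predicted total consumption is
#' `pf(T) * duration * mass^0.8` and observed total consumption is
#' `MO2 * duration * mass^0.8`, so the duration and mass terms cancel and
#' the log residual reduces to `log(MO2 / pf(T))`. These points sit at
#' `lambda = 0` for plotting or reporting alongside the breakpoint fit; they
#' are never included in the regression itself.
#'
#' @param mo2_table Stable-trial MO2 table from [estimate_mo2_table()].
#' @param fit A `tpc_fit` or [tpc_params()].
#' @param log_base Logarithm base.
#' @return Data frame with `trial_id`, `lambda_c_per_min` (all 0) and
#'   `residual` (`NA` where MO2 or pf is non-positive).
#' @export
overlay_stable_residuals <- function(mo2_table, fit, log_base = exp(1)) {
  params <- if (inherits(fit, "tpc_fit")) fit$params else fit
  pf <- rezende_pf(mo2_table$mean_temp_c, params)
  data.frame(trial_id = mo2_table$trial_id,
             lambda_c_per_min = 0,
             residual = compute_residual(mo2_table$mo2, pf, log_base),
             stringsAsFactors = FALSE)
}
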