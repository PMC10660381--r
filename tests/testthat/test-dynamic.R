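# TPC integration, ramp predictions and log residuals.

test_that("integration matches the closed-form antiderivative below the
           threshold", {
  p <- printed_params()
  # int C Q^(T/10) dT = C * 10/ln(Q) * Q^(T/10)
  closed <- p$ce * (10 / log(p$q10)) * (p$q10^1.5 - p$q10^1.0)
  got <- integrate_tpc(p, 10, 15)
  expect_equal(got, closed, tolerance = 1e-6 * closed)
  expect_equal(got, 5.2637099, tolerance = 1e-5)
  expect_identical(integrate_tpc(p, 14, 14), 0)
})

test_that("integration across the threshold matches a brute-force
           trapezoid oracle", {
  p <- printed_params()
  grid <- seq(10, 21, length.out = 1e5 + 1)
  y <- rezende_pf(grid, p)
  trap <- sum((utils::head(y, -1) + utils::tail(y, -1)) / 2) * diff(grid[1:2])
  got <- integrate_tpc(p, 10, 21)
  expect_equal(got, trap, tolerance = 1e-6 * abs(trap))
})

test_that("integration is antisymmetric and additive over subintervals", {
  set.seed(9)
  for (i in 1:20) {
    p <- tpc_params(runif(1, 0.1, 1), runif(1, 1.5, 5), runif(1, 12, 20),
                    runif(1, 0, 0.1))
    t1 <- runif(1, 5, 25); t2 <- runif(1, 5, 25); tm <- runif(1, 5, 25)
    expect_equal(integrate_tpc(p, t1, t2), -integrate_tpc(p, t2, t1),
                 tolerance = 1e-9)
    expect_equal(integrate_tpc(p, t1, t2),
                 integrate_tpc(p, t1, tm) + integrate_tpc(p, tm, t2),
                 tolerance = 1e-7)
  }
})

test_that("ramp prediction converts the integral with rate and mass", {
  expect_equal(predicted_total_o2(5.264, 5 / 60, 1e-4),
               5.264 * 60 / 5 * 10^(-3.2), tolerance = 1e-10)
  expect_equal(predicted_total_o2(5.264, 5 / 60, 1e-4), 0.0398564,
               tolerance = 1e-5)
  # cooling: both integral and rate flip sign, prediction stays positive
  expect_equal(predicted_total_o2(-5.264, -5 / 60, 1e-4),
               predicted_total_o2(5.264, 5 / 60, 1e-4), tolerance = 1e-12)
  # halving |lambda| doubles exposure, hence consumption
  expect_equal(predicted_total_o2(5.264, 2.5 / 60, 1e-4),
               2 * predicted_total_o2(5.264, 5 / 60, 1e-4), tolerance = 1e-12)
  expect_error(predicted_total_o2(5.264, 0, 1e-4), "lambda is zero")
})

test_that("log residuals behave as log(observed/predicted)", {
  expect_equal(compute_residual(0.04, 0.04), 0)
  expect_equal(compute_residual(exp(1) * 0.04, 0.04), 1, tolerance = 1e-12)
  expect_equal(compute_residual(0.0437, 0.0399), 0.0909718, tolerance = 1e-6)
  expect_equal(compute_residual(100, 10, log_base = 10), 1, tolerance = 1e-12)
  expect_true(is.na(compute_residual(-0.005, 0.04)))
  expect_true(is.na(compute_residual(0.04, 0)))
})

test_that("budgets cover exactly the ramping trials and flag undefined
           residuals instead of aborting", {
  cfg <- clean_config(seed = 13)
  ex <- simulate_experiment(cfg, stable_reps = 1L, ramp_reps = 1L)
  budgets <- build_budgets(ex$roster, ex$traces, cfg$tpc)
  expect_equal(nrow(budgets), 16)
  expect_false(any(budgets$trial_id %in%
                     ex$roster$trial_id[ex$roster$direction == "stable"]))
  ok <- !budgets$excluded
  expect_true(all(is.finite(budgets$residual[ok])))

  # residuals reflect only the first/last-five estimation window: each DO
  # sample is the start DO minus the consumption integral up to that time,
  # so the exact expected observed total is the difference of the
  # window-averaged integrals (independent quadrature oracle)
  for (i in which(ok)) {
    id <- budgets$trial_id[i]
    tr <- ex$traces[[id]]
    meta <- ex$roster[ex$roster$trial_id == id, ]
    lam <- meta$lambda_c_per_min
    consumed <- function(t)   # mg consumed by time t
      integrate_tpc(cfg$tpc, meta$t_start_c, meta$t_start_c + lam * t) / lam *
        meta$mass_kg^0.8
    expected_obs <- mean(vapply(utils::tail(tr$time_min, 5), consumed, 0)) -
      mean(vapply(utils::head(tr$time_min, 5), consumed, 0))
    pred_full <- predicted_total_o2(
      integrate_tpc(cfg$tpc, meta$t_start_c, meta$t_end_c), lam, meta$mass_kg)
    # slack covers the simulator's fixed-step forward-integration error
    expect_equal(budgets$residual[i], log(expected_obs / pred_full),
                 tolerance = 1e-4, label = id)
  }

  # a trace too short for the estimator is excluded with a reason
  short_id <- budgets$trial_id[1]
  ex$traces[[short_id]] <- do_series(0:5, rep(8, 6) - 0.01 * (0:5),
                                     rep(15, 6), trial_id = short_id)
  budgets2 <- build_budgets(ex$roster, ex$traces, cfg$tpc)
  row <- budgets2[budgets2$trial_id == short_id, ]
  expect_true(row$excluded)
  expect_match(row$reason, "too short")
})

test_that("noise-free observed consumption matches the prediction over the
           estimator's effective window", {
  cfg <- clean_config()
  for (spec in list(c(10, 21, 5), c(21, 10, 10), c(15, 21, 1))) {
    meta <- ramp_meta(spec[1], spec[2], spec[3], mass = 1.2e-4)
    tr <- simulate_trial(meta, cfg)
    v_eff <- effective_volume(0.2, 1.2e-4)
    obs <- observed_total_o2(tr, v_eff)
    lam <- meta$lambda_c_per_min
    t_lo <- spec[1] + lam * mean(utils::head(tr$time_min, 5))
    t_hi <- spec[1] + lam * mean(utils::tail(tr$time_min, 5))
    pred <- predicted_total_o2(integrate_tpc(cfg$tpc, t_lo, t_hi), lam, 1.2e-4)
    expect_equal(obs, pred, tolerance = 1e-3 / pred)
  }
})
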