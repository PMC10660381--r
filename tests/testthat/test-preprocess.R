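# Blank-slope fitting, background correction, hypoxia truncation and
# exclusion accounting.

test_that("blank slope is the OLS line through the blank trace", {
  b <- do_series(c(0, 1, 2), c(8.0, 7.9, 7.8), rep(NA_real_, 3))
  fit <- fit_blank_slope(b)
  expect_equal(fit$slope, -0.1, tolerance = 1e-12)
  expect_equal(fit$intercept, 8.0, tolerance = 1e-12)

  flat <- do_series(0:5, rep(8, 6), rep(NA_real_, 6))
  expect_equal(fit_blank_slope(flat)$slope, 0, tolerance = 1e-14)
})

test_that("blank slope matches the closed-form normal equations on a noisy
           line", {
  set.seed(42)
  tt <- seq(0, 199, by = 1)
  y <- 8.5 - 0.002 * tt + rnorm(200, 0, 0.01)
  fit <- fit_blank_slope(do_series(tt, y, rep(NA_real_, 200)))
  # normal-equations oracle
  sxx <- sum((tt - mean(tt))^2)
  slope_hat <- sum((tt - mean(tt)) * (y - mean(y))) / sxx
  expect_equal(fit$slope, slope_hat, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(y) - slope_hat * mean(tt), tolerance = 1e-12)
})

test_that("background correction adds back bacterially consumed oxygen", {
  s <- linear_series(-0.005, n = 101, do0 = 8)
  expect_equal(correct_background(s, 0)$do_mg_l, s$do_mg_l)

  # raw 7.5 at t = 100 under blank slope -0.001 corrects to 7.6
  corr <- correct_background(s, -0.001)
  expect_equal(corr$do_mg_l[s$time_min == 100],
               s$do_mg_l[s$time_min == 100] + 0.1, tolerance = 1e-12)
  expect_identical(corr$time_min, s$time_min)
  expect_equal(nrow(corr), nrow(s))
})

test_that("correcting a simulated animal+background trace recovers the
           animal-only slope", {
  cfg_both <- sim_config(noise_sd = 0, blank_slope = -0.001,
                         individual_sd = 0, seed = 3)
  cfg_animal <- sim_config(noise_sd = 0, blank_slope = 0,
                           individual_sd = 0, seed = 3)
  meta <- stable_meta(temp = 18, mass = 1.5e-4)
  with_bg <- simulate_trial(meta, cfg_both)
  animal_only <- simulate_trial(meta, cfg_animal)
  corrected <- correct_background(with_bg, -0.001)
  slope <- function(s) coef(lm(do_mg_l ~ time_min, data = s))[[2]]
  expect_equal(slope(corrected), slope(animal_only), tolerance = 1e-12)
})

test_that("hypoxia truncation cuts before the first sample under threshold", {
  s <- do_series(0:4, c(8, 6, 4, 2.9, 2.5), rep(15, 5))
  out <- truncate_hypoxia(s)
  expect_equal(out$do_mg_l, c(8, 6, 4))
  expect_true(was_truncated(out))
  # prefix property
  expect_identical(out$time_min, s$time_min[1:3])

  ok <- do_series(0:3, c(8, 6, 4, 3.5), rep(15, 4))
  out2 <- truncate_hypoxia(ok)
  expect_equal(nrow(out2), 4)
  expect_false(was_truncated(out2))

  # a sample exactly at the threshold is the last usable one
  edge <- do_series(0:2, c(5, 3.0, 2.9), rep(15, 3))
  out3 <- truncate_hypoxia(edge)
  expect_equal(out3$do_mg_l, c(5, 3.0))

  expect_error(truncate_hypoxia(do_series(0:2, c(2.5, 2, 1), rep(15, 3))),
               "below threshold")
  expect_error(truncate_hypoxia(do_series(0:2, c(3.5, 2, 1), rep(15, 3))),
               "fewer than 2")
})

test_that("exclusions remove listed trials and keep per-direction accounts
           conserved", {
  ex <- simulate_experiment(sim_config(seed = 8), stable_reps = 1L,
                            ramp_reps = 1L)
  roster <- ex$roster
  # empty list leaves the roster unchanged
  res0 <- apply_exclusions(roster)
  expect_equal(nrow(res0$roster), nrow(roster))
  expect_true(all(res0$counts$removed == 0))

  listed <- data.frame(trial_id = roster$trial_id[roster$direction == "heating"][1:2],
                       reason = c("died", "timer set incorrectly"))
  res <- apply_exclusions(roster, listed)
  expect_equal(nrow(res$roster), nrow(roster) - 2)
  expect_equal(res$counts$removed[res$counts$direction == "heating"], 2L)
  expect_equal(res$counts$measured, res$counts$analysed + res$counts$removed)

  expect_error(apply_exclusions(roster, data.frame(trial_id = "nope", reason = "x")),
               "unknown trial id")
})

test_that("ramping trials with non-positive observed consumption are
           auto-excluded", {
  roster <- rbind(trial_meta_from_id("82T2110R10", mass_kg = 1e-4),
                  trial_meta_from_id("84T2110R10", mass_kg = 1e-4),
                  trial_meta_from_id("36T2110R10", mass_kg = 1e-4),
                  trial_meta_from_id("1T1021R5", mass_kg = 1e-4))
  budgets <- data.frame(
    trial_id = roster$trial_id,
    observed_mg = c(-0.005, -0.02, -0.008, 0.04),
    stringsAsFactors = FALSE)
  res <- apply_exclusions(roster, budgets = budgets)
  expect_setequal(res$removals$trial_id,
                  c("82T2110R10", "84T2110R10", "36T2110R10"))
  expect_equal(res$counts$analysed[res$counts$direction == "cooling"], 0L)
  expect_equal(res$counts$analysed[res$counts$direction == "heating"], 1L)
})
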