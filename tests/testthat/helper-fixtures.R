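# Shared fixtures: deterministic configurations and tiny trial builders.

printed_params <- function() tpc_params(ce = 0.26, q10 = 3.03, t_th = 17.93, d = 0.05)

# a noiseless, drift-free, no-individual-variation configuration
clean_config <- function(seed = 1L, ...) {
  sim_config(noise_sd = 0, blank_slope = 0, individual_sd = 0, seed = seed, ...)
}

stable_meta <- function(temp = 15, mass = 1e-4, id = NULL, animal = 1L) {
  if (is.null(id)) id <- sprintf("%dT%02d%02dR0", animal, temp, temp)
  trial_meta(id, animal, "stable", temp, temp, 0, mass, 0.2)
}

ramp_meta <- function(t_start, t_end, rate_hr, mass = 1e-4, animal = 1L) {
  lab <- sub("^0\\.", "0.", format(rate_hr))
  id <- sprintf("%dT%02d%02dR%s", animal, t_start, t_end, lab)
  trial_meta_from_id(id, mass_kg = mass)
}

# linear DO trace with a known slope
linear_series <- function(slope, n = 20, t_step = 1, do0 = 9, temp = 15,
                          id = "t") {
  tt <- seq(0, by = t_step, length.out = n)
  do_series(tt, do0 + slope * tt, rep(temp, n), trial_id = id,
            sampling_rate = 1 / t_step)
}

# budgets table straight from the piecewise residual model (no traces)
synthetic_budgets <- function(n, a = 0, b_heat = 7.71, b_cool = -2.73,
                              sigma = 0.05, seed = 1L) {
  set.seed(seed)
  lam <- sample(c(design_rates_hr, -design_rates_hr) / 60, n, replace = TRUE)
  y <- a + b_heat * lam * (lam > 0) + b_cool * lam * (lam < 0) +
    rnorm(n, 0, sigma)
  data.frame(trial_id = sprintf("s%03d", seq_len(n)),
             lambda_c_per_min = lam, residual = y,
             observed_mg = exp(y), predicted_mg = 1, excluded = FALSE,
             stringsAsFactors = FALSE)
}

design_rates_hr <- c(0.5, 1, 5, 10)
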