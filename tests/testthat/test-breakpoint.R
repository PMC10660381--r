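# Bayesian breakpoint-at-zero regression: null behaviour, parameter
# recovery, agreement with closed-form OLS and an external MCMC oracle.

test_that("null residuals give a posterior concentrated at zero", {
  b <- synthetic_budgets(24, a = 0, b_heat = 0, b_cool = 0, sigma = 0,
                         seed = 2)
  post <- fit_breakpoint(b, seed = 1)
  m <- post$summary$mean[match(c("a", "b_heat", "b_cool"), post$summary$parameter)]
  expect_true(all(abs(m) < 0.01))
  expect_lt(post$summary$mean[post$summary$parameter == "sigma"], 0.01)
})

test_that("the sampler recovers known heating and cooling slopes", {
  b <- synthetic_budgets(100, a = 0, b_heat = 7.71, b_cool = -2.73,
                         sigma = 0.05, seed = 5)
  post <- fit_breakpoint(b, seed = 3)
  s <- post$summary
  truth <- c(a = 0, b_heat = 7.71, b_cool = -2.73, sigma = 0.05)
  for (p in names(truth)) {
    row <- s[s$parameter == p, ]
    expect_lt(abs(row$mean - truth[[p]]), 3 * row$sd + 1e-6, label = p)
  }
  expect_gte(post$p_heat_pos, 0.99)
  expect_gte(post$p_cool_neg, 0.99)
  expect_true(post$converged)
  expect_true(all(post$rhat <= 1.01))
  expect_true(all(post$ess >= 400))
  expect_equal(nrow(post$draws), 4 * 1000)
})

test_that("with effectively flat priors the posterior mean matches the
           piecewise OLS closed form", {
  b <- synthetic_budgets(60, a = 0.1, b_heat = 3, b_cool = -1, sigma = 0.2,
                         seed = 8)
  lam <- b$lambda_c_per_min
  X <- cbind(1, lam * (lam > 0), lam * (lam < 0))
  ols <- solve(crossprod(X), crossprod(X, b$residual))
  post <- fit_breakpoint(b, priors = list(coef_sd = 1e4, sigma_sd = 10),
                         seed = 2)
  s <- post$summary
  for (i in 1:3) {
    row <- s[i, ]
    mcse <- row$sd / sqrt(row$ess)
    expect_lt(abs(row$mean - ols[i]), 4 * mcse, label = row$parameter)
  }
})

test_that("posterior scales equivariantly when residuals are doubled", {
  b <- synthetic_budgets(80, a = 0.05, b_heat = 2, b_cool = -1, sigma = 0.1,
                         seed = 4)
  b2 <- b; b2$residual <- 2 * b$residual
  flat <- list(coef_sd = 1e4, sigma_sd = 50)
  m1 <- fit_breakpoint(b, priors = flat, seed = 6)$summary$mean[1:3]
  m2 <- fit_breakpoint(b2, priors = flat, seed = 6)$summary$mean[1:3]
  expect_equal(m2, 2 * m1, tolerance = 0.02)
})

test_that("the in-package sampler agrees with an independent JAGS fit", {
  b <- synthetic_budgets(50, a = -0.1, b_heat = 5, b_cool = -2, sigma = 0.15,
                         seed = 10)
  post <- fit_breakpoint(b, seed = 11)
  library(rjags)
  model_txt <- "model {
    for (i in 1:n) {
      mu[i] <- a + bh * lh[i] + bc * lc[i]
      y[i] ~ dnorm(mu[i], tau)
    }
    a ~ dnorm(0, 1e-4); bh ~ dnorm(0, 1e-4); bc ~ dnorm(0, 1e-4)
    sigma ~ dnorm(0, 0.01) T(0,)
    tau <- 1 / (sigma * sigma)
  }"
  lam <- b$lambda_c_per_min
  jm <- jags.model(textConnection(model_txt),
                   data = list(y = b$residual, lh = lam * (lam > 0),
                               lc = lam * (lam < 0), n = nrow(b)),
                   inits = list(.RNG.name = "base::Wichmann-Hill",
                                .RNG.seed = 42),
                   n.chains = 1, quiet = TRUE)
  update(jm, 1000, progress.bar = "none")
  sm <- coda.samples(jm, c("a", "bh", "bc", "sigma"), 4000,
                     progress.bar = "none")
  jags_mean <- colMeans(as.matrix(sm))[c("a", "bh", "bc", "sigma")]
  ours <- post$summary$mean[match(c("a", "b_heat", "b_cool", "sigma"),
                                  post$summary$parameter)]
  sds <- post$summary$sd[match(c("a", "b_heat", "b_cool", "sigma"),
                               post$summary$parameter)]
  # both are MC estimates of the same posterior
  expect_true(all(abs(ours - jags_mean) < 0.15 * sds + 0.01))
})

test_that("posterior probabilities carry Monte Carlo uncertainty", {
  expect_equal(posterior_prob(rep(1, 2000), function(x) x > 0)$prob, 1)
  set.seed(31)
  sym <- rnorm(20000)
  p <- posterior_prob(sym, function(x) x > 0)
  expect_lt(abs(p$prob - 0.5), 3 * p$mcse + 0.01)
  tail <- posterior_prob(sym, function(x) x > 1.96)
  expect_lt(abs(tail$prob - 0.025), 3 * tail$mcse + 0.002)
  expect_error(posterior_prob(rnorm(100), function(x) x > 0), "1000 draws")
})

test_that("stable-trial overlay residuals sit at lambda zero and cancel
           duration", {
  cfg <- clean_config(seed = 17)
  meta <- stable_meta(temp = 18, mass = 1e-4)
  tr <- simulate_trial(meta, cfg)
  mo2_tab <- estimate_mo2(tr, 1e-4, 0.2)
  ov <- overlay_stable_residuals(mo2_tab, cfg$tpc)
  expect_equal(ov$lambda_c_per_min, 0)
  expect_equal(ov$residual, 0, tolerance = 1e-9)

  # halving the duration leaves the residual unchanged (obs/pred ratio)
  cfg2 <- clean_config(seed = 17, stable_duration_min = 45)
  tr2 <- simulate_trial(meta, cfg2)
  ov2 <- overlay_stable_residuals(estimate_mo2(tr2, 1e-4, 0.2), cfg$tpc)
  expect_equal(ov2$residual, ov$residual, tolerance = 1e-9)

  # noisy stable residuals scatter symmetrically when the TPC is the truth
  cfg3 <- sim_config(noise_sd = 0.02, individual_sd = 0, blank_slope = 0,
                     seed = 23)
  signs <- vapply(1:40, function(i) {
    m <- stable_meta(temp = 15, mass = 1.5e-4, animal = i)
    t3 <- simulate_trial(m, cfg3, seed = 500 + i)
    sign(overlay_stable_residuals(estimate_mo2(t3, 1.5e-4, 0.2), cfg3$tpc)$residual)
  }, numeric(1))
  bt <- binom.test(sum(signs > 0), length(signs))
  expect_gt(bt$p.value, 0.01)
})

test_that("the regression refuses underpowered designs and excludes stable
           points", {
  b <- synthetic_budgets(30, seed = 3)
  b$lambda_c_per_min[b$lambda_c_per_min < 0] <- abs(b$lambda_c_per_min[b$lambda_c_per_min < 0])
  expect_error(fit_breakpoint(b), "3 heating and 3 cooling")
  # lambda = 0 rows (stable overlays) are never part of the fit
  b2 <- synthetic_budgets(40, seed = 6)
  with_stable <- rbind(b2, data.frame(trial_id = "st", lambda_c_per_min = 0,
                                      residual = 5, observed_mg = 1,
                                      predicted_mg = 1, excluded = FALSE))
  p1 <- fit_breakpoint(b2, seed = 9)
  p2 <- fit_breakpoint(with_stable, seed = 9)
  expect_equal(p1$summary$mean, p2$summary$mean, tolerance = 1e-12)
})
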