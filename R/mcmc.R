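# MCMC utilities: univariate slice sampler (Neal 2003, stepping out with
# shrinkage), split-Rhat, and effective sample size by Geyer's initial
# monotone sequence estimator. Internal.

slice_sample1 <- function(x0, logf, w = 1, max_steps = 50L) {
  fx0 <- logf(x0)
  logy <- fx0 - stats::rexp(1)
  u <- stats::runif(1)
  l <- x0 - w * u
  r <- l + w
  j <- floor(max_steps * stats::runif(1))
  k <- max_steps - 1L - j
  while (j > 0L && logf(l) > logy) { l <- l - w; j <- j - 1L }
  while (k > 0L && logf(r) > logy) { r <- r + w; k <- k - 1L }
  repeat {
    x1 <- stats::runif(1, l, r)
    if (logf(x1) >= logy) return(x1)
    if (x1 < x0) l <- x1 else r <- x1
  }
}

# chains: iterations x chains matrix of post-warmup draws for one parameter
split_rhat <- function(chains) {
  n <- nrow(chains)
  half <- floor(n / 2)
  sub <- cbind(chains[seq_len(half), , drop = FALSE],
               chains[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2L, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  if (w == 0) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

ess_geyer_one <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  maxlag <- min(n - 2L, 2000L)
  rho <- as.numeric(stats::acf(x, lag.max = maxlag, plot = FALSE,
                               demean = TRUE)$acf)[-1L]
  # sums of adjacent pairs; truncate at first non-positive, enforce monotone
  npair <- floor(length(rho) / 2)
  if (npair < 1L) return(n)
  gam <- rho[2 * seq_len(npair) - 1L] + rho[2 * seq_len(npair)]
  pos <- which(gam <= 0)
  if (length(pos) > 0L) gam <- gam[seq_len(pos[1L] - 1L)]
  if (length(gam) > 1L) gam <- cummin(gam)
  tau <- 1 + 2 * sum(gam)
  max(1, min(n, n / max(tau, 1e-12)))
}

ess_chains <- function(chains) {
  sum(apply(chains, 2L, ess_geyer_one))
}
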