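# Independent brute-force oracles used to validate the analytic
# implementations. These deliberately avoid the package's own code paths.

# Random small meta-analytic dataset (plain tibble).
random_dataset <- function(k = sample(2:10, 1),
                           mu = runif(1, -0.5, 1),
                           tau = runif(1, 0, 0.6)) {
  v <- runif(k, 0.005, 0.2)
  theta <- rnorm(k, mu, tau)
  tibble::tibble(estimate = rnorm(k, theta, sqrt(v)), variance = v)
}

# Cochran's Q by direct summation.
oracle_q <- function(y, v) {
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  sum(w * (y - ybar)^2)
}

# DerSimonian-Laird by direct formula evaluation.
oracle_dl <- function(y, v) {
  k <- length(y)
  w <- 1 / v
  q <- oracle_q(y, v)
  max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

# Paule-Mandel by plain interval bisection on the generalized Q equation.
oracle_pm <- function(y, v, lo = 0, hi = 100, iters = 60) {
  k <- length(y)
  gq <- function(t2) {
    w <- 1 / (v + t2)
    mu <- sum(w * y) / sum(w)
    sum(w * (y - mu)^2) - (k - 1)
  }
  if (gq(lo) <= 0) return(0)
  while (gq(hi) > 0) hi <- hi * 2
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (gq(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# REML by two-stage grid search over the restricted log-likelihood
# (coarse pass over [0, upper], then a fine pass at step `fine`).
oracle_reml_grid <- function(y, v, upper = 10, coarse = 0.01, fine = 1e-4) {
  ll <- function(t2) {
    w <- 1 / (v + t2)
    mu <- sum(w * y) / sum(w)
    -0.5 * sum(log(v + t2)) - 0.5 * log(sum(w)) - 0.5 * sum(w * (y - mu)^2)
  }
  grid <- seq(0, upper, by = coarse)
  vals <- vapply(grid, ll, numeric(1))
  best <- grid[which.max(vals)]
  grid2 <- seq(max(0, best - coarse), best + coarse, by = fine)
  vals2 <- vapply(grid2, ll, numeric(1))
  grid2[which.max(vals2)]
}

# Inverse-variance pooled mean at a given tau2, written out longhand.
oracle_pooled_mean <- function(y, v, tau2) {
  num <- 0
  den <- 0
  for (i in seq_along(y)) {
    num <- num + y[i] / (v[i] + tau2)
    den <- den + 1 / (v[i] + tau2)
  }
  num / den
}

# Pearson r via explicit covariance / variance sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy / sqrt(sxx * syy)
}

# Per-phenomenon naive pooled means for a suite (convenience, not an oracle).
split_suite_fits <- function(suite, tau2_method = "PM") {
  sapply(split(suite$studies, suite$studies$phenomenon_id)[
    unique(suite$studies$phenomenon_id)], function(d) {
      fit_random_effects(d, tau2_method = tau2_method)$mu
    })
}

# Selection-ratio correction by literally replicating each
# non-affirmative study `eta` times (integer eta) and taking the naive
# inverse-variance mean at a fixed tau2.
oracle_eta_replication <- function(y, v, affirmative, eta, tau2) {
  reps <- ifelse(affirmative, 1L, as.integer(eta))
  yy <- rep(y, reps)
  vv <- rep(v, reps)
  oracle_pooled_mean(yy, vv, tau2)
}
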