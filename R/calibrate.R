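#' Calibrated (shrunken) estimates of study-level population effects
#'
#' Shrinks each study's point estimate toward the pooled mean by its
#' empirical-Bayes factor,
#' \deqn{\hat\gamma_i = \hat\mu + \frac{\hat\tau^2}{\hat\tau^2 + v_i}
#'       (y_i - \hat\mu),}
#' so that the empirical distribution of the \eqn{\hat\gamma_i} estimates the
#' distribution of population effects across studies. The raw point
#' estimates overstate that dispersion because they carry sampling error on
#' top of genuine heterogeneity; the shrinkage removes the sampling-error
#' component. With \eqn{\hat\tau^2 = 0} every calibrated estimate collapses
#' to the pooled mean; as \eqn{v_i \to 0} a study's calibrated estimate
#' approaches its own point estimate.
#'
#' @param data A study table (columns `estimate`, `variance`).
#' @param fit Optionally, a [fit_random_effects()] result computed from
#'   `data`; fitted on the fly when omitted.
#' @param tau2_method Heterogeneity estimator used when `fit` is omitted.
#' @return The input tibble with a `calibrated` column appended.
#' @export
#' @examples
#' d <- data.frame(estimate = c(0.1, 0.5), variance = c(0.1, 0.1))
#' calibrate_estimates(d, tau2_method = "DL")
calibrate_estimates <- function(data, fit = NULL,
                                tau2_method = c("PM", "DL", "REML")) {
  tau2_method <- match.arg(tau2_method)
  data <- validate_studies(data, require_k = 1L)
  if (is.null(fit)) {
    fit <- fit_random_effects(data, tau2_method = tau2_method)
  }
  if (!inherits(fit, "meta_fit")) {
    stop("`fit` must be a `meta_fit` object.", call. = FALSE)
  }
  if (fit$k != nrow(data)) {
    stop("`fit` was computed from ", fit$k, " studies but `data` has ",
         nrow(data), "; they must match.", call. = FALSE)
  }
  shrink <- fit$tau2 / (fit$tau2 + data$variance)
  data$calibrated <- fit$mu + shrink * (data$estimate - fit$mu)
  attr(data, "source_fit") <- fit
  data
}

#' Proportion of calibrated population effects at or below a threshold
#'
#' Given calibrated estimates, returns the fraction that are as small as, or
#' smaller than, a threshold `q` — typically the multi-laboratory
#' replication (MLR) estimate. The comparison is inclusive (<=). This is a
#' plug-in estimate of the share of population effects in the meta-analysed
#' literature that are no larger than `q`.
#'
#' @param calibrated A [calibrate_estimates()] result (or any data frame
#'   with a `calibrated` column), or a bare numeric vector of calibrated
#'   estimates.
#' @param q Threshold on the SMD scale; must be finite.
#' @return A single proportion in \[0, 1\].
#' @export
#' @examples
#' prop_below_threshold(c(0.1, 0.2, 0.3), q = 0.2)  # 2/3
prop_below_threshold <- function(calibrated, q) {
  if (is.data.frame(calibrated)) {
    if (!"calibrated" %in% names(calibrated)) {
      stop("`calibrated` must contain a `calibrated` column; ",
           "see calibrate_estimates().", call. = FALSE)
    }
    calibrated <- calibrated$calibrated
  }
  if (length(calibrated) == 0L) {
    stop("`calibrated` must be non-empty.", call. = FALSE)
  }
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q)) {
    stop("`q` must be a single finite number.", call. = FALSE)
  }
  mean(calibrated <= q)
}

#' BCa bootstrap interval for the proportion-below-threshold statistic
#'
#' Estimates the proportion of population effects at or below `q` together
#' with a bias-corrected and accelerated (BCa) bootstrap confidence
#' interval. Studies are resampled with replacement at the study level (the
#' only level available from study-level data); each bootstrap replicate
#' refits the random-effects meta-analysis with the same tau^2 estimator,
#' recalibrates, and recomputes the proportion. The bias-correction term
#' z0 comes from the bootstrap distribution's position relative to the
#' point estimate (with ties split at half weight) and the acceleration from
#' a leave-one-out jackknife.
#'
#' The interval is flagged non-estimable — bounds `NA`, `ci_estimable =
#' FALSE` — when the bootstrap distribution is degenerate (all replicates
#' identical, or the whole distribution on one side of the estimate so that
#' z0 is infinite), and for single-study inputs. Estimable bounds are
#' clipped to \[0, 1\].
#'
#' @param data A study table (columns `estimate`, `variance`).
#' @param q Threshold on the SMD scale (e.g. the MLR estimate, treated as a
#'   fixed known value).
#' @param n_boot Number of bootstrap replicates; at least 200 (default 1000).
#' @param seed Integer RNG seed; required so every interval is reproducible.
#' @param tau2_method Heterogeneity estimator used in every (re)fit.
#' @param level Confidence level (default 0.95).
#' @param ci_method `"bca"` (default) or `"percentile"` (plain bootstrap
#'   quantiles, mainly for method-comparison studies).
#' @return A one-row tibble: `phat`, `ci_low`, `ci_high`, `ci_estimable`,
#'   `threshold`, `n_boot`, `seed`.
#' @export
#' @examples
#' d <- data.frame(estimate = rnorm(10, 0.4, 0.3), variance = rep(0.05, 10))
#' bca_ci_for_proportion(d, q = 0.2, n_boot = 200, seed = 1)
bca_ci_for_proportion <- function(data, q, n_boot = 1000, seed,
                                  tau2_method = c("PM", "DL", "REML"),
                                  level = 0.95,
                                  ci_method = c("bca", "percentile")) {
  tau2_method <- match.arg(tau2_method)
  ci_method <- match.arg(ci_method)
  data <- validate_studies(data, require_k = 1L)
  if (n_boot < 200) {
    stop("`n_boot` must be at least 200 for a stable BCa interval.",
         call. = FALSE)
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("`seed` must be supplied as a single integer.", call. = FALSE)
  }
  y <- data$estimate
  v <- data$variance
  k <- length(y)

  stat <- function(yy, vv) {
    tau2 <- tau2_vec(yy, vv, tau2_method)
    mu <- pool_vec(yy, vv, tau2)$mu
    gamma <- mu + tau2 / (tau2 + vv) * (yy - mu)
    mean(gamma <= q)
  }
  t0 <- stat(y, v)

  result <- function(lo, hi, estimable) {
    tibble::tibble(
      phat = t0, ci_low = lo, ci_high = hi, ci_estimable = estimable,
      threshold = q, n_boot = as.integer(n_boot), seed = as.integer(seed)
    )
  }
  if (k < 2L) return(result(NA_real_, NA_real_, FALSE))

  boot_t <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(k, k, replace = TRUE)
      stat(y[idx], v[idx])
    }, numeric(1))
  })

  if (stats::sd(boot_t) == 0) return(result(NA_real_, NA_real_, FALSE))
  alpha <- 1 - level
  if (ci_method == "percentile") {
    ci <- stats::quantile(boot_t, c(alpha / 2, 1 - alpha / 2),
                          names = FALSE, type = 6)
    ci <- pmin(pmax(ci, 0), 1)
    return(result(ci[1], ci[2], TRUE))
  }
  frac_below <- (sum(boot_t < t0) + 0.5 * sum(boot_t == t0)) / n_boot
  z0 <- stats::qnorm(frac_below)
  if (!is.finite(z0)) return(result(NA_real_, NA_real_, FALSE))

  jack <- vapply(seq_len(k), function(i) stat(y[-i], v[-i]), numeric(1))
  jm <- mean(jack)
  denom <- sum((jm - jack)^2)^1.5
  accel <- if (denom > 0) sum((jm - jack)^3) / (6 * denom) else 0

  z <- stats::qnorm(c(alpha / 2, 1 - alpha / 2))
  adj <- stats::pnorm(z0 + (z0 + z) / (1 - accel * (z0 + z)))
  if (any(!is.finite(adj))) return(result(NA_real_, NA_real_, FALSE))
  ci <- stats::quantile(boot_t, probs = adj, names = FALSE, type = 6)
  ci <- pmin(pmax(ci, 0), 1)
  result(ci[1], ci[2], TRUE)
}
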