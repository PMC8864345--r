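#' Cochran's Q heterogeneity statistic
#'
#' Computes the classical heterogeneity statistic
#' \deqn{Q = \sum_i w_i (y_i - \bar y_w)^2, \quad w_i = 1 / v_i,}
#' where \eqn{\bar y_w} is the inverse-variance weighted mean of the study
#' estimates. Under homogeneity Q is approximately chi-squared on k - 1
#' degrees of freedom; it is the building block of the moment-based
#' heterogeneity estimators.
#'
#' @param data A study table with columns `estimate` and `variance`
#'   (see [validate_studies()]).
#' @return A single non-negative number. A single study (no contrast) gives 0.
#' @export
#' @examples
#' cochran_q(data.frame(estimate = c(0, 0.5, 1), variance = rep(0.1, 3)))
cochran_q <- function(data) {
  data <- validate_studies(data, require_k = 1L)
  w <- 1 / data$variance
  ybar <- sum(w * data$estimate) / sum(w)
  max(0, sum(w * (data$estimate - ybar)^2))
}

#' Estimate between-study heterogeneity variance (tau-squared)
#'
#' Estimates the variance tau^2 of true effects across studies, beyond
#' within-study sampling error, by one of three standard estimators:
#'
#' * `"DL"` — DerSimonian-Laird moment estimator,
#'   \eqn{\hat\tau^2 = \max(0, (Q - (k-1)) / C)} with
#'   \eqn{C = \sum w_i - \sum w_i^2 / \sum w_i}, \eqn{w_i = 1/v_i}.
#' * `"PM"` — Paule-Mandel: the value of tau^2 at which the generalized
#'   Q statistic \eqn{\sum w_i^*(y_i - \hat\mu^*)^2} (with
#'   \eqn{w_i^* = 1/(v_i + \tau^2)}) equals its expectation k - 1, found by
#'   bracketed root-finding; 0 when Q <= k - 1. This is the package default
#'   throughout, matching the convention of the publication-bias
#'   sensitivity-analysis literature.
#' * `"REML"` — maximizer of the restricted log-likelihood over tau^2 >= 0.
#'
#' @param data A study table (columns `estimate`, `variance`).
#' @param method One of `"PM"`, `"DL"`, `"REML"`.
#' @param tol Convergence tolerance for PM root-finding and REML
#'   optimization (on the tau^2 scale).
#' @param upper Upper bracket for the PM root / REML search, in SMD^2 units.
#'   The default 100 is far beyond any plausible heterogeneity of
#'   standardized mean differences.
#' @return A single non-negative number (SMD^2 units). With fewer than two
#'   studies the estimate is 0, with a warning.
#' @export
#' @examples
#' d <- data.frame(estimate = c(0, 0.5, 1), variance = rep(0.1, 3))
#' estimate_tau2(d, method = "DL")  # 0.15
estimate_tau2 <- function(data, method = c("PM", "DL", "REML"),
                          tol = 1e-8, upper = 100) {
  method <- match.arg(method)
  data <- validate_studies(data, require_k = 1L)
  k <- nrow(data)
  if (k < 2L) {
    warning("tau^2 is not identifiable from ", k,
            " study; returning 0.", call. = FALSE)
    return(0)
  }
  tau2_vec(data$estimate, data$variance, method, tol = tol, upper = upper)
}

# Vectorized heterogeneity estimators used by the public API and by
# bootstrap loops that need to skip data-frame validation.
tau2_vec <- function(y, v, method, tol = 1e-8, upper = 100) {
  k <- length(y)
  if (k < 2L) return(0)

  if (method == "DL") {
    w <- 1 / v
    ybar <- sum(w * y) / sum(w)
    q <- sum(w * (y - ybar)^2)
    c_const <- sum(w) - sum(w^2) / sum(w)
    return(max(0, (q - (k - 1)) / c_const))
  }

  if (method == "PM") {
    # Generalized Q minus its expectation; decreasing in tau2.
    f <- function(tau2) {
      w <- 1 / (v + tau2)
      mu <- sum(w * y) / sum(w)
      sum(w * (y - mu)^2) - (k - 1)
    }
    if (f(0) <= 0) return(0)
    hi <- upper
    while (f(hi) > 0 && hi < 1e8) hi <- hi * 10
    if (f(hi) > 0) {
      stop("Paule-Mandel estimating equation has no root below ", hi,
           "; check the input variances.", call. = FALSE)
    }
    return(stats::uniroot(f, c(0, hi), tol = tol)$root)
  }

  # REML: profile restricted log-likelihood in tau2.
  ll <- function(tau2) reml_loglik(tau2, y, v)
  # Expand the search interval if the optimum sits at the boundary.
  hi <- upper
  opt <- stats::optimize(ll, c(0, hi), maximum = TRUE, tol = tol)
  while (hi - opt$maximum < 1e-3 && hi < 1e8) {
    hi <- hi * 10
    opt <- stats::optimize(ll, c(0, hi), maximum = TRUE, tol = tol)
  }
  if (ll(0) >= opt$objective) return(0)
  max(0, opt$maximum)
}

# Pooled mean and SE at a given tau2 (vector interface).
pool_vec <- function(y, v, tau2) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  list(mu = mu, se = sqrt(1 / sum(w)))
}

# Restricted log-likelihood of a random-effects model, profiled over mu.
reml_loglik <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * sum(log(v + tau2)) - 0.5 * log(sum(w)) - 0.5 * sum(w * (y - mu)^2)
}

#' Fit a random-effects meta-analysis
#'
#' Pools study-level standardized mean differences under the random-effects
#' model \eqn{y_i \sim N(\theta_i, v_i)}, \eqn{\theta_i \sim N(\mu, \tau^2)}.
#' The pooled mean is the inverse-variance weighted average with weights
#' \eqn{w_i^* = 1/(v_i + \hat\tau^2)}; its standard error is
#' \eqn{(\sum w_i^*)^{-1/2}}. With `interval_method = "wald_z"` the 95%
#' interval is mu +/- 1.96 se; `"hksj"` applies the Knapp-Hartung variance
#' rescaling with a t(k - 1) critical value.
#'
#' A single-study input is legal (publication-bias worst-case analyses can
#' leave one study): the fit passes through the study's estimate and
#' standard error and is flagged `low_k`.
#'
#' @param data A study table (columns `estimate`, `variance`).
#' @param tau2_method Heterogeneity estimator passed to [estimate_tau2()].
#' @param interval_method `"wald_z"` (default) or `"hksj"`.
#' @param tau2 Optional fixed tau^2 overriding estimation (e.g. 0 for a
#'   fixed-effect fit, or to match heterogeneity handling across fits).
#' @param level Confidence level (default 0.95).
#' @return An object of class `meta_fit`: a list with elements `mu`, `tau2`,
#'   `se_mu`, `ci_low`, `ci_high`, `k`, `q_stat`, `tau2_method`,
#'   `interval_method`, `level`, `low_k`, and the input `data`. Use
#'   [generics::tidy()] / [generics::glance()] for tibble views.
#' @export
#' @examples
#' d <- data.frame(estimate = c(0.2, 0.4), variance = c(0.01, 0.01))
#' fit_random_effects(d, tau2 = 0)$mu  # 0.3
fit_random_effects <- function(data,
                               tau2_method = c("PM", "DL", "REML"),
                               interval_method = c("wald_z", "hksj"),
                               tau2 = NULL, level = 0.95) {
  tau2_method <- match.arg(tau2_method)
  interval_method <- match.arg(interval_method)
  data <- validate_studies(data, require_k = 1L)
  k <- nrow(data)
  y <- data$estimate
  v <- data$variance

  if (is.null(tau2)) {
    tau2 <- if (k >= 2L) estimate_tau2(data, method = tau2_method) else 0
  } else {
    stopifnot(is.numeric(tau2), length(tau2) == 1L, tau2 >= 0)
  }

  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  se <- sqrt(1 / sum(w))
  alpha <- 1 - level

  if (k >= 2L && interval_method == "hksj") {
    # Knapp-Hartung: rescale the variance by the weighted residual
    # mean square and use a t(k-1) reference.
    se_hk <- sqrt(sum(w * (y - mu)^2) / ((k - 1) * sum(w)))
    crit <- stats::qt(1 - alpha / 2, df = k - 1)
    ci <- mu + c(-1, 1) * crit * se_hk
    se_report <- se_hk
  } else {
    crit <- stats::qnorm(1 - alpha / 2)
    ci <- mu + c(-1, 1) * crit * se
    se_report <- se
  }

  structure(
    list(
      mu = mu, tau2 = tau2, se_mu = se_report,
      ci_low = ci[1], ci_high = ci[2],
      k = k, q_stat = cochran_q(data),
      tau2_method = tau2_method, interval_method = interval_method,
      level = level, low_k = k < 2L, data = data
    ),
    class = "meta_fit"
  )
}

#' @export
print.meta_fit <- function(x, ...) {
  cat("Random-effects meta-analysis (", x$k, " studies)\n", sep = "")
  cat(sprintf("  pooled mean : %.4f [%.4f, %.4f] (%d%% %s)\n",
              x$mu, x$ci_low, x$ci_high, round(100 * x$level),
              x$interval_method))
  cat(sprintf("  se(mean)    : %.4f\n", x$se_mu))
  cat(sprintf("  tau^2 (%s)  : %.4f   Q = %.3f\n",
              x$tau2_method, x$tau2, x$q_stat))
  if (x$low_k) cat("  note: single-study passthrough fit\n")
  invisible(x)
}

#' Tidy a random-effects meta-analysis fit
#'
#' @param x A `meta_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the pooled estimate, its standard error and
#'   confidence bounds.
#' @export
tidy.meta_fit <- function(x, ...) {
  tibble::tibble(
    term = "mu",
    estimate = x$mu,
    std.error = x$se_mu,
    conf.low = x$ci_low,
    conf.high = x$ci_high
  )
}

#' One-row model summary of a meta-analysis fit
#'
#' @param x A `meta_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `mu`, `se_mu`, `ci_low`, `ci_high`, `tau2`,
#'   `q_stat`, `k`, `tau2_method`, `interval_method`.
#' @export
glance.meta_fit <- function(x, ...) {
  tibble::tibble(
    mu = x$mu, se_mu = x$se_mu, ci_low = x$ci_low, ci_high = x$ci_high,
    tau2 = x$tau2, q_stat = x$q_stat, k = x$k,
    tau2_method = x$tau2_method, interval_method = x$interval_method
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
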