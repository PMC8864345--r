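#' Classify studies as affirmative or non-affirmative
#'
#' Under the significance-based selection model of publication bias,
#' a study is *affirmative* when it is statistically significant at the
#' two-sided level `alpha` **and** its point estimate is in the expected
#' (positive) direction — i.e. \eqn{y_i/\sqrt{v_i} > z_{1-\alpha/2}}.
#' Everything else — non-significant results, and significant results in
#' the unexpected direction — is *non-affirmative*. The selection model
#' assumes affirmative studies are more likely to be published, with no
#' further selection on the size of the point estimate.
#'
#' @param data A study table (columns `estimate`, `variance`).
#' @param alpha Two-sided significance level in (0, 1); default 0.05
#'   (equivalent to a one-tailed 0.025 test in the positive direction).
#' @return The input tibble with `z` and `affirmative` columns appended.
#' @export
#' @examples
#' classify_studies(data.frame(estimate = c(0.5, -0.5, 0.1),
#'                             variance = c(0.04, 0.01, 0.04)))
classify_studies <- function(data, alpha = 0.05) {
  data <- validate_studies(data, require_k = 1L)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single number in (0, 1).", call. = FALSE)
  }
  crit <- stats::qnorm(1 - alpha / 2)
  data$z <- data$estimate / sqrt(data$variance)
  data$affirmative <- data$z > crit
  attr(data, "alpha") <- alpha
  data
}

sensitivity_row <- function(eta, corrected_mu, worst_case_mu,
                            n_aff, n_nonaff, estimable, tau2) {
  tibble::tibble(
    eta = eta,
    corrected_mu = corrected_mu,
    worst_case_mu = worst_case_mu,
    n_affirmative = as.integer(n_aff),
    n_nonaffirmative = as.integer(n_nonaff),
    estimable = estimable,
    tau2 = tau2
  )
}

#' Publication-bias-corrected pooled estimate at a known selection ratio
#'
#' Corrects the random-effects pooled mean for publication bias under the
#' assumption that affirmative studies were `eta` times more likely to be
#' published than non-affirmative ones. Because published non-affirmative
#' studies are then a random sample of the underlying non-affirmative
#' population, the correction simply up-weights each non-affirmative study
#' by `eta`:
#' \deqn{\hat\mu_\eta = \frac{\sum_i \tilde w_i y_i}{\sum_i \tilde w_i},
#'   \quad \tilde w_i = \frac{\eta^{1[\text{non-affirmative}]}}
#'   {v_i + \hat\tau^2}.}
#' The heterogeneity \eqn{\hat\tau^2} is estimated once on the full
#' published dataset and held fixed inside the reweighting, so `eta` acts
#' on the mean only; `eta = 1` reproduces the naive random-effects mean
#' exactly. For the `eta -> Inf` limit use [worst_case_estimate()].
#'
#' @param data A study table (columns `estimate`, `variance`).
#' @param eta Selection ratio, a single finite number >= 1.
#' @param tau2_method Heterogeneity estimator for the full-data tau^2.
#' @param alpha Two-sided significance level for [classify_studies()].
#' @return A one-row tibble: `eta`, `corrected_mu`, `worst_case_mu` (`NA`;
#'   see [worst_case_estimate()]), `n_affirmative`, `n_nonaffirmative`,
#'   `estimable`, `tau2`.
#' @export
#' @examples
#' d <- data.frame(estimate = c(0.6, 0.5, 0.05), variance = rep(0.04, 3))
#' corrected_estimate(d, eta = 5)
corrected_estimate <- function(data, eta,
                               tau2_method = c("PM", "DL", "REML"),
                               alpha = 0.05) {
  tau2_method <- match.arg(tau2_method)
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta < 1) {
    stop("`eta` must be a single finite number >= 1 ",
         "(use worst_case_estimate() for the infinite-selection limit).",
         call. = FALSE)
  }
  cls <- classify_studies(data, alpha = alpha)
  tau2 <- tau2_vec(cls$estimate, cls$variance, tau2_method)
  w <- ifelse(cls$affirmative, 1, eta) / (cls$variance + tau2)
  mu <- sum(w * cls$estimate) / sum(w)
  sensitivity_row(eta, mu, NA_real_,
                  sum(cls$affirmative), sum(!cls$affirmative),
                  TRUE, tau2)
}

#' Worst-case publication-bias pooled estimate
#'
#' The worst-case scenario lets affirmative studies be *infinitely* more
#' likely to be published than non-affirmative ones. In that limit the
#' bias-corrected estimate is simply an ordinary random-effects
#' meta-analysis of the non-affirmative studies alone, discarding every
#' affirmative study. The heterogeneity is re-estimated on that subset
#' (it is an ordinary meta-analysis of the subset); a single remaining
#' study gives the passthrough fit. With no non-affirmative study the
#' worst case is not statistically feasible and the result is flagged
#' `estimable = FALSE` rather than raising an error.
#'
#' @param data A study table (columns `estimate`, `variance`).
#' @param tau2_method Heterogeneity estimator for the subset fit.
#' @param alpha Two-sided significance level for [classify_studies()].
#' @return A one-row tibble: `eta` (`Inf`), `corrected_mu` (`NA`),
#'   `worst_case_mu`, `n_affirmative`, `n_nonaffirmative`, `estimable`,
#'   `tau2` (subset estimate, `NA` when not estimable).
#' @export
#' @examples
#' d <- data.frame(estimate = c(0.6, 0.5, 0.05), variance = rep(0.04, 3))
#' worst_case_estimate(d)
worst_case_estimate <- function(data,
                                tau2_method = c("PM", "DL", "REML"),
                                alpha = 0.05) {
  tau2_method <- match.arg(tau2_method)
  cls <- classify_studies(data, alpha = alpha)
  nonaff <- cls[!cls$affirmative, , drop = FALSE]
  n_aff <- sum(cls$affirmative)
  if (nrow(nonaff) == 0L) {
    return(sensitivity_row(Inf, NA_real_, NA_real_,
                           n_aff, 0L, FALSE, NA_real_))
  }
  fit <- fit_random_effects(nonaff, tau2_method = tau2_method)
  sensitivity_row(Inf, NA_real_, fit$mu, n_aff, nrow(nonaff), TRUE, fit$tau2)
}
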