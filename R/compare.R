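#' Correlate meta-analytic and replication effect size estimates
#'
#' Computes the Pearson correlation between per-phenomenon meta-analytic
#' (MA) pooled estimates and the corresponding multi-laboratory replication
#' (MLR) estimates, with a Fisher z-transform confidence interval
#' (\eqn{\mathrm{atanh}(r) \pm z_{1-\alpha/2}/\sqrt{n-3}}, back-transformed)
#' and a two-sided p-value from \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n - 2
#' degrees of freedom. Also returns the ordinary least-squares fit of the
#' MLR estimates on the MA estimates, the summary line of the standard
#' MA-versus-MLR scatter.
#'
#' @param pairs A data frame with one row per phenomenon.
#' @param ma,mlr Column names (strings) holding the MA and MLR estimates;
#'   defaults `"ma_estimate"` and `"mlr_estimate"`.
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `r`, `ci_low`, `ci_high`, `p_value`, `slope`,
#'   `intercept`, `n`.
#' @export
#' @examples
#' pairs <- data.frame(ma_estimate = c(0.2, 0.4, 0.6, 0.8),
#'                     mlr_estimate = c(0.1, 0.35, 0.4, 0.7))
#' correlate_estimates(pairs)
correlate_estimates <- function(pairs, ma = "ma_estimate",
                                mlr = "mlr_estimate", level = 0.95) {
  stopifnot(is.data.frame(pairs))
  for (col in c(ma, mlr)) {
    if (!col %in% names(pairs)) {
      stop("`pairs` is missing column `", col, "`.", call. = FALSE)
    }
  }
  x <- pairs[[ma]]
  y <- pairs[[mlr]]
  n <- length(x)
  if (n < 3L) {
    stop("At least 3 phenomenon pairs are needed for a correlation (got ",
         n, ").", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Correlation is undefined: zero variance in the ",
         if (stats::sd(x) == 0) "MA" else "MLR", " estimates.",
         call. = FALSE)
  }
  r <- stats::cor(x, y)
  ci <- fisher_z_ci(r, n, level)
  p <- cor_t_pvalue(r, n)
  slope <- stats::cov(x, y) / stats::var(x)
  tibble::tibble(
    r = r, ci_low = ci[1], ci_high = ci[2], p_value = p,
    slope = slope, intercept = mean(y) - slope * mean(x), n = as.integer(n)
  )
}

#' Fisher z-transform confidence interval for a Pearson correlation
#'
#' @param r Pearson correlation in (-1, 1).
#' @param n Number of pairs, > 3.
#' @param level Confidence level.
#' @return Length-2 numeric vector (lower, upper).
#' @export
#' @examples
#' fisher_z_ci(0.72, 15)  # approximately [0.32, 0.90]
fisher_z_ci <- function(r, n, level = 0.95) {
  stopifnot(abs(r) < 1, n > 3)
  z <- atanh(r)
  half <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}

#' Two-sided t-test p-value for a Pearson correlation
#'
#' @inheritParams fisher_z_ci
#' @return Two-sided p-value from t on n - 2 degrees of freedom.
#' @export
cor_t_pvalue <- function(r, n) {
  stopifnot(abs(r) < 1, n > 2)
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t_stat), df = n - 2)
}

#' Summarize worst-case publication-bias results across phenomena
#'
#' Applies the inclusion filter used in cross-phenomenon sensitivity
#' analyses — phenomena whose naive pooled estimate exceeds the MLR
#' estimate *and* whose worst-case analysis is statistically feasible (at
#' least one non-affirmative study) — and summarizes the included set:
#' mean naive and worst-case estimates, the mean of per-phenomenon
#' worst/naive ratios (and, separately, the ratio of the two means, which
#' generally differs), the mean absolute naive-minus-worst difference, and
#' the fractions of included phenomena whose worst-case estimate still
#' exceeds the MLR estimate and the null (strict inequalities on point
#' estimates). The median proportion-below-threshold statistic is reported
#' both over all phenomena with a defined value and over the included set.
#'
#' @param per_phenomenon A data frame with one row per phenomenon and
#'   columns `naive_mu`, `mlr_estimate`, `worst_case_mu`, `worst_estimable`
#'   (logical), and optionally `phat`.
#' @return A one-row tibble: `n_analyzed`, `mean_naive`, `mean_worst_case`,
#'   `mean_ratio`, `ratio_of_means`, `mean_abs_diff`,
#'   `prop_worst_exceeds_mlr`, `prop_worst_exceeds_null`,
#'   `median_phat`, `median_phat_included`. With an empty included set,
#'   `n_analyzed` is 0 and all statistics except `median_phat` are `NA`.
#' @export
#' @examples
#' tab <- data.frame(naive_mu = c(0.4, 0.2), mlr_estimate = c(0.1, 0.05),
#'                   worst_case_mu = c(0.2, 0.1),
#'                   worst_estimable = c(TRUE, TRUE), phat = c(0.2, 0.3))
#' sensitivity_summary(tab)
sensitivity_summary <- function(per_phenomenon) {
  stopifnot(is.data.frame(per_phenomenon))
  needed <- c("naive_mu", "mlr_estimate", "worst_case_mu", "worst_estimable")
  missing_cols <- setdiff(needed, names(per_phenomenon))
  if (length(missing_cols)) {
    stop("`per_phenomenon` is missing column(s): ",
         paste(missing_cols, collapse = ", "), ".", call. = FALSE)
  }
  tab <- tibble::as_tibble(per_phenomenon)
  if (!"phat" %in% names(tab)) tab$phat <- NA_real_

  included <- tab$worst_estimable & tab$naive_mu > tab$mlr_estimate
  included[is.na(included)] <- FALSE
  inc <- tab[included, , drop = FALSE]
  n_inc <- nrow(inc)

  median_phat_all <- stats::median(tab$phat, na.rm = TRUE)
  if (all(is.na(tab$phat))) median_phat_all <- NA_real_

  if (n_inc == 0L) {
    return(tibble::tibble(
      n_analyzed = 0L, mean_naive = NA_real_, mean_worst_case = NA_real_,
      mean_ratio = NA_real_, ratio_of_means = NA_real_,
      mean_abs_diff = NA_real_, prop_worst_exceeds_mlr = NA_real_,
      prop_worst_exceeds_null = NA_real_,
      median_phat = median_phat_all, median_phat_included = NA_real_
    ))
  }

  median_phat_inc <- stats::median(inc$phat, na.rm = TRUE)
  if (all(is.na(inc$phat))) median_phat_inc <- NA_real_

  tibble::tibble(
    n_analyzed = n_inc,
    mean_naive = mean(inc$naive_mu),
    mean_worst_case = mean(inc$worst_case_mu),
    mean_ratio = mean(inc$worst_case_mu / inc$naive_mu),
    ratio_of_means = mean(inc$worst_case_mu) / mean(inc$naive_mu),
    mean_abs_diff = mean(abs(inc$naive_mu - inc$worst_case_mu)),
    prop_worst_exceeds_mlr = mean(inc$worst_case_mu > inc$mlr_estimate),
    prop_worst_exceeds_null = mean(inc$worst_case_mu > 0),
    median_phat = median_phat_all,
    median_phat_included = median_phat_inc
  )
}

#' Run the full meta-analysis versus MLR comparison pipeline
#'
#' For every phenomenon: fits the naive random-effects meta-analysis,
#' classifies studies as affirmative/non-affirmative, computes the
#' calibrated proportion of population effects at or below the MLR
#' estimate with its BCa bootstrap interval, runs the worst-case
#' publication-bias analysis (and, optionally, eta-corrected estimates for
#' a list of selection ratios), and flags inclusion in the cross-phenomenon
#' sensitivity summary. Then assembles the correlation of MA versus MLR
#' estimates (when at least 3 phenomena are present) and the
#' [sensitivity_summary()]. The whole report is a deterministic function
#' of the inputs and `seed` (per-phenomenon bootstrap seeds are derived
#' from it).
#'
#' @param studies Either a study table with a `phenomenon_id` column, or a
#'   `phenomenon_suite` from [simulate_phenomenon_suite()] (in which case
#'   `mlr` is taken from the suite).
#' @param mlr A data frame with columns `phenomenon_id`, `mlr_estimate`,
#'   `mlr_variance`; ignored when `studies` is a suite.
#' @param tau2_method,interval_method Passed to [fit_random_effects()].
#' @param alpha Two-sided significance level for study classification.
#' @param n_boot Bootstrap replicates for each phenomenon's BCa interval.
#' @param seed Integer seed governing all bootstrap randomness.
#' @param eta Optional numeric vector of finite selection ratios for
#'   [corrected_estimate()].
#' @return An `mlr_comparison` object: a list with `per_phenomenon` (one
#'   row per phenomenon), `correlation` (one-row tibble, or `NULL` below 3
#'   phenomena), `summary` (one-row tibble), `corrected` (long tibble over
#'   `eta`, possibly empty), and `config`.
#' @export
#' @examples
#' suite <- simulate_phenomenon_suite(5, suite_template(), seed = 1)
#' run_full_comparison(suite, n_boot = 200, seed = 2)
run_full_comparison <- function(studies, mlr = NULL,
                                tau2_method = c("PM", "DL", "REML"),
                                interval_method = c("wald_z", "hksj"),
                                alpha = 0.05, n_boot = 1000, seed,
                                eta = numeric(0)) {
  tau2_method <- match.arg(tau2_method)
  interval_method <- match.arg(interval_method)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("`seed` must be supplied as a single integer.", call. = FALSE)
  }
  if (inherits(studies, "phenomenon_suite")) {
    mlr <- studies$mlr
    studies <- studies$studies
  }
  stopifnot(is.data.frame(studies), is.data.frame(mlr))
  if (!"phenomenon_id" %in% names(studies)) {
    stop("`studies` must have a `phenomenon_id` column.", call. = FALSE)
  }
  for (col in c("phenomenon_id", "mlr_estimate", "mlr_variance")) {
    if (!col %in% names(mlr)) {
      stop("`mlr` is missing column `", col, "`.", call. = FALSE)
    }
  }
  if (any(mlr$mlr_variance <= 0)) {
    stop("All `mlr_variance` values must be > 0.", call. = FALSE)
  }
  groups <- split_phenomena(validate_studies(studies))
  ids <- names(groups)
  missing_mlr <- setdiff(ids, as.character(mlr$phenomenon_id))
  if (length(missing_mlr)) {
    stop("No MLR estimate for phenomenon: ",
         paste(missing_mlr, collapse = ", "), ".", call. = FALSE)
  }
  mlr_lut <- mlr[match(ids, as.character(mlr$phenomenon_id)), , drop = FALSE]

  per <- purrr::map2(groups, seq_along(groups), function(d, j) {
    id <- ids[j]
    tryCatch({
      fit <- fit_random_effects(d, tau2_method = tau2_method,
                                interval_method = interval_method)
      cls <- classify_studies(d, alpha = alpha)
      q <- mlr_lut$mlr_estimate[j]
      # id-based (not position-based) child seed, so report statistics
      # are invariant to the ordering of input phenomena
      id_hash <- sum(utf8ToInt(id) * seq_along(utf8ToInt(id)))
      child_seed <- as.integer((as.numeric(seed) + 7919 * id_hash) %%
                                 .Machine$integer.max)
      prop <- bca_ci_for_proportion(d, q = q, n_boot = n_boot,
                                    seed = child_seed,
                                    tau2_method = tau2_method)
      wc <- worst_case_estimate(d, tau2_method = tau2_method, alpha = alpha)
      tibble::tibble(
        phenomenon_id = id,
        k = nrow(d),
        naive_mu = fit$mu, naive_ci_low = fit$ci_low,
        naive_ci_high = fit$ci_high, tau2 = fit$tau2,
        mlr_estimate = q, mlr_variance = mlr_lut$mlr_variance[j],
        n_affirmative = sum(cls$affirmative),
        n_nonaffirmative = sum(!cls$affirmative),
        phat = prop$phat, phat_ci_low = prop$ci_low,
        phat_ci_high = prop$ci_high, phat_ci_estimable = prop$ci_estimable,
        worst_case_mu = wc$worst_case_mu, worst_estimable = wc$estimable,
        included = wc$estimable & fit$mu > q
      )
    }, error = function(e) {
      stop("Phenomenon `", id, "`: ", conditionMessage(e), call. = FALSE)
    })
  })
  per <- dplyr::bind_rows(per)

  corrected <- tibble::tibble(
    phenomenon_id = character(), eta = numeric(), corrected_mu = numeric()
  )
  if (length(eta)) {
    corrected <- purrr::map(seq_along(groups), function(j) {
      rows <- purrr::map(sort(unique(eta)), function(e) {
        res <- corrected_estimate(groups[[j]], eta = e,
                                  tau2_method = tau2_method, alpha = alpha)
        tibble::tibble(phenomenon_id = ids[j], eta = e,
                       corrected_mu = res$corrected_mu)
      })
      dplyr::bind_rows(rows)
    })
    corrected <- dplyr::bind_rows(corrected)
  }

  correlation <- NULL
  if (nrow(per) >= 3L) {
    correlation <- correlate_estimates(
      data.frame(ma_estimate = per$naive_mu, mlr_estimate = per$mlr_estimate)
    )
  }

  structure(
    list(
      per_phenomenon = per,
      correlation = correlation,
      summary = sensitivity_summary(per),
      corrected = corrected,
      config = list(tau2_method = tau2_method,
                    interval_method = interval_method, alpha = alpha,
                    n_boot = as.integer(n_boot), seed = as.integer(seed),
                    eta = eta)
    ),
    class = "mlr_comparison"
  )
}

#' @export
print.mlr_comparison <- function(x, ...) {
  cat("Meta-analysis vs multi-laboratory replication comparison\n")
  cat("  phenomena:", nrow(x$per_phenomenon),
      "| tau^2:", x$config$tau2_method,
      "| alpha:", x$config$alpha,
      "| n_boot:", x$config$n_boot,
      "| seed:", x$config$seed, "\n\n")
  if (!is.null(x$correlation)) {
    with(x$correlation, cat(sprintf(
      "  MA~MLR correlation: r = %.2f [%.2f, %.2f], p = %.3g; MLR = %.2f + %.2f * MA\n",
      r, ci_low, ci_high, p_value, intercept, slope)))
  }
  s <- x$summary
  if (s$n_analyzed > 0) {
    cat(sprintf("  worst-case summary over %d included phenomena:\n",
                s$n_analyzed))
    cat(sprintf("    mean naive = %.3f, mean worst-case = %.3f (mean ratio %.2f)\n",
                s$mean_naive, s$mean_worst_case, s$mean_ratio))
    cat(sprintf("    worst-case > MLR: %.0f%%; worst-case > 0: %.0f%%\n",
                100 * s$prop_worst_exceeds_mlr,
                100 * s$prop_worst_exceeds_null))
  } else {
    cat("  no phenomena passed the sensitivity-summary inclusion filter\n")
  }
  if (!is.na(s$median_phat)) {
    cat(sprintf("  median %% of population effects <= MLR estimate: %.0f%%\n",
                100 * s$median_phat))
  }
  invisible(x)
}

#' Tidy the per-phenomenon comparison table
#'
#' @param x An `mlr_comparison` object.
#' @param ... Unused.
#' @return The per-phenomenon tibble.
#' @export
tidy.mlr_comparison <- function(x, ...) x$per_phenomenon

#' One-row summary of a full comparison
#'
#' @param x An `mlr_comparison` object.
#' @param ... Unused.
#' @return The cross-phenomenon summary joined with the correlation row
#'   (correlation columns `NA` when fewer than 3 phenomena).
#' @export
glance.mlr_comparison <- function(x, ...) {
  corr <- x$correlation
  if (is.null(corr)) {
    corr <- tibble::tibble(r = NA_real_, ci_low = NA_real_,
                           ci_high = NA_real_, p_value = NA_real_,
                           slope = NA_real_, intercept = NA_real_,
                           n = NA_integer_)
  }
  dplyr::bind_cols(
    x$summary,
    dplyr::rename(corr, r_ci_low = "ci_low", r_ci_high = "ci_high",
                  r_p_value = "p_value", n_phenomena = "n")
  )
}
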