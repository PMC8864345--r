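#' Configuration for the synthetic meta-analysis generator
#'
#' Bundles and validates the parameters of the generating model used by
#' [simulate_meta()] and [simulate_mlr()]: true effects
#' \eqn{\theta_i \sim N(\mu, \tau^2)}, within-study sampling error
#' \eqn{y_i \sim N(\theta_i, v_i)} with the two-arm SMD approximation
#' \eqn{v_i \approx 4 / n_i} and per-study total sample sizes drawn
#' uniformly from `n_range`, and one-sided significance-based publication
#' selection: affirmative studies (significant at two-sided `alpha`, in the
#' positive direction) are always published, non-affirmative studies are
#' published independently with probability `1 / eta`. A companion
#' multi-laboratory replication (MLR) draws one high-precision estimate
#' around `mlr_mu`, which may differ from `mu_true` to emulate worlds where
#' the meta-analysis/MLR discrepancy is not publication bias.
#'
#' The defaults describe a typical published psychology literature:
#' moderate mean effect, heterogeneity in the middle of the range observed
#' across real meta-analyses (tau^2 around 0.1), per-study samples of
#' 30-150 participants, and an MLR of several thousand participants.
#'
#' @param mu_true Mean true effect (SMD).
#' @param tau2_true Between-study variance of true effects (SMD^2), >= 0.
#' @param k_published Number of published studies to generate, >= 1.
#' @param eta Selection ratio >= 1 (1 = no publication bias).
#' @param n_range Two-element range of per-study total sample sizes.
#' @param alpha Two-sided significance level defining affirmative studies.
#' @param mlr_mu True effect measured by the MLR (defaults to `mu_true`).
#' @param mlr_n Total MLR sample size, >= 100.
#' @param seed Optional integer seed; when set, the generator functions are
#'   pure functions of the configuration.
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(mu_true = 0.2, tau2_true = 0.05, eta = 5, seed = 1)
sim_config <- function(mu_true = 0.3, tau2_true = 0.1, k_published = 20,
                       eta = 1, n_range = c(30, 150), alpha = 0.05,
                       mlr_mu = mu_true, mlr_n = 5000, seed = NULL) {
  stopifnot(
    is.numeric(mu_true), length(mu_true) == 1L, is.finite(mu_true),
    is.numeric(tau2_true), length(tau2_true) == 1L, tau2_true >= 0,
    is.numeric(k_published), length(k_published) == 1L, k_published >= 1,
    is.numeric(eta), length(eta) == 1L, eta >= 1,
    is.numeric(n_range), length(n_range) == 2L, all(n_range >= 4),
    n_range[1] <= n_range[2],
    is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
    is.numeric(mlr_mu), length(mlr_mu) == 1L, is.finite(mlr_mu),
    is.numeric(mlr_n), length(mlr_n) == 1L, mlr_n >= 100
  )
  structure(
    list(mu_true = mu_true, tau2_true = tau2_true,
         k_published = as.integer(k_published), eta = eta,
         n_range = n_range, alpha = alpha,
         mlr_mu = mlr_mu, mlr_n = mlr_n, seed = seed),
    class = "sim_config"
  )
}

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

#' Simulate one published meta-analytic literature
#'
#' Draws candidate studies from the generating model in [sim_config()] and
#' applies significance-based publication selection until `k_published`
#' studies are published. Selection depends only on a study's affirmative
#' status — never on the size of its point estimate beyond that — matching
#' the selection model assumed by the bias-correction methods, so
#' [corrected_estimate()] at the true `eta` is unbiased for `mu_true`.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`; with neither set the
#'   current RNG stream is used (so suite-level generators can manage one
#'   stream).
#' @param max_draws Candidate-study budget before generation is abandoned
#'   with an error (guards against unattainable configurations such as a
#'   huge `eta` with a strongly negative `mu_true`).
#' @return A tibble of published studies: `study_label`, `estimate`,
#'   `variance`, `n_per_study`, `theta_true` (the study's true effect,
#'   retained for recovery tests), `affirmative`.
#' @export
#' @examples
#' simulate_meta(sim_config(eta = 5, seed = 42))
simulate_meta <- function(config, seed = NULL,
                          max_draws = max(1e5, 1000 * config$k_published)) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  with_seed_maybe(seed, {
    crit <- stats::qnorm(1 - config$alpha / 2)
    k_target <- config$k_published
    published <- list()
    n_pub <- 0L
    drawn <- 0L
    while (n_pub < k_target) {
      batch <- max(64L, ceiling((k_target - n_pub) * 1.5))
      if (drawn + batch > max_draws) batch <- max_draws - drawn
      if (batch <= 0L) {
        stop("Could not generate ", k_target, " published studies within ",
             max_draws, " draws (", n_pub, " published after ", drawn,
             " candidates); eta = ", config$eta, ", mu_true = ",
             config$mu_true, ".", call. = FALSE)
      }
      n_i <- sample(seq(config$n_range[1], config$n_range[2]), batch,
                    replace = TRUE)
      v <- 4 / n_i
      theta <- stats::rnorm(batch, config$mu_true, sqrt(config$tau2_true))
      y <- stats::rnorm(batch, theta, sqrt(v))
      affirm <- y / sqrt(v) > crit
      publish <- affirm | (stats::runif(batch) < 1 / config$eta)
      drawn <- drawn + batch
      keep <- which(publish)
      if (length(keep)) {
        published[[length(published) + 1L]] <- tibble::tibble(
          estimate = y[keep], variance = v[keep],
          n_per_study = n_i[keep], theta_true = theta[keep],
          affirmative = affirm[keep]
        )
        n_pub <- n_pub + length(keep)
      }
    }
    out <- dplyr::bind_rows(published)[seq_len(k_target), ]
    out$study_label <- paste0("study_", seq_len(k_target))
    dplyr::relocate(out, "study_label")
  })
}

#' Simulate a multi-laboratory replication estimate
#'
#' Draws one high-precision estimate
#' \eqn{y_{\mathrm{mlr}} \sim N(\mu_{\mathrm{mlr}}, 4/n_{\mathrm{mlr}})},
#' the two-arm SMD variance approximation at the MLR's total sample size.
#' MLRs are preregistered, so no publication selection is applied.
#'
#' @inheritParams simulate_meta
#' @return A one-row tibble: `mlr_estimate`, `mlr_variance`.
#' @export
#' @examples
#' simulate_mlr(sim_config(mlr_mu = 0.25, mlr_n = 8000, seed = 7))
simulate_mlr <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  with_seed_maybe(seed, {
    v <- 4 / config$mlr_n
    tibble::tibble(
      mlr_estimate = stats::rnorm(1, config$mlr_mu, sqrt(v)),
      mlr_variance = v
    )
  })
}

#' Template for a cross-phenomenon simulation suite
#'
#' Describes the distributions from which per-phenomenon parameters are
#' drawn by [simulate_phenomenon_suite()]: mean effects
#' \eqn{\mu_j \sim N(}`mu_mean`, `mu_sd`\eqn{^2)}, heterogeneity
#' \eqn{\tau^2_j \sim U(}`tau2_range`\eqn{)} (the default range brackets
#' the spread observed across real psychology meta-analyses), a common
#' selection ratio `eta`, study counts uniform on `k_range`, and MLR true
#' effects \eqn{\mu_j + }`mlr_offset` — a discrepancy knob for emulating
#' worlds where the meta-analysis/MLR gap is substantive rather than
#' selection-driven.
#'
#' @param mu_mean,mu_sd Mean and SD of per-phenomenon true mean effects.
#' @param tau2_range Range of per-phenomenon heterogeneity (SMD^2).
#' @param eta Selection ratio shared by all phenomena.
#' @param k_range Range of published-study counts per phenomenon.
#' @param n_range Per-study sample-size range.
#' @param alpha Two-sided significance level.
#' @param mlr_offset Shift of each MLR true effect away from its
#'   phenomenon's `mu_true` (0 = MLR measures the same effect).
#' @param mlr_n Total MLR sample size.
#' @return A `suite_template` list.
#' @export
suite_template <- function(mu_mean = 0.4, mu_sd = 0.2,
                           tau2_range = c(0, 0.22), eta = 1,
                           k_range = c(10, 40), n_range = c(30, 150),
                           alpha = 0.05, mlr_offset = 0, mlr_n = 5000) {
  stopifnot(
    is.numeric(mu_mean), is.numeric(mu_sd), mu_sd >= 0,
    length(tau2_range) == 2L, all(tau2_range >= 0),
    tau2_range[1] <= tau2_range[2],
    eta >= 1, length(k_range) == 2L, k_range[1] >= 1,
    k_range[1] <= k_range[2], is.numeric(mlr_offset), mlr_n >= 100
  )
  structure(
    list(mu_mean = mu_mean, mu_sd = mu_sd, tau2_range = tau2_range,
         eta = eta, k_range = k_range, n_range = n_range, alpha = alpha,
         mlr_offset = mlr_offset, mlr_n = mlr_n),
    class = "suite_template"
  )
}

#' Simulate a suite of phenomena with paired MLR estimates
#'
#' Generates `n_phenomena` independent meta-analytic literatures and one
#' MLR estimate each, with per-phenomenon parameters drawn from a
#' [suite_template()]. This emulates the structure of cross-phenomenon
#' comparisons in which each of a set of psychological phenomena has both
#' a published meta-analysis and a preregistered multi-laboratory
#' replication. Ground-truth parameters are retained for recovery tests.
#'
#' @param n_phenomena Number of phenomena, >= 2.
#' @param template A [suite_template()].
#' @param seed Integer seed; the suite is a pure function of
#'   `(template, n_phenomena, seed)`.
#' @return A `phenomenon_suite` list of three tibbles: `studies`
#'   (study-level rows with `phenomenon_id`), `mlr` (one row per
#'   phenomenon: `mlr_estimate`, `mlr_variance`), and `truth`
#'   (per-phenomenon `mu_true`, `tau2_true`, `eta`, `mlr_mu`, `k`).
#' @export
#' @examples
#' suite <- simulate_phenomenon_suite(15, suite_template(eta = 10), seed = 1)
simulate_phenomenon_suite <- function(n_phenomena = 15,
                                      template = suite_template(),
                                      seed) {
  stopifnot(inherits(template, "suite_template"),
            is.numeric(n_phenomena), n_phenomena >= 2)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("`seed` must be supplied as a single integer.", call. = FALSE)
  }
  n_phenomena <- as.integer(n_phenomena)
  withr::with_seed(as.integer(seed), {
    ids <- sprintf("phen_%02d", seq_len(n_phenomena))
    mu <- stats::rnorm(n_phenomena, template$mu_mean, template$mu_sd)
    tau2 <- stats::runif(n_phenomena, template$tau2_range[1],
                         template$tau2_range[2])
    k <- sample(seq(template$k_range[1], template$k_range[2]),
                n_phenomena, replace = TRUE)
    pieces <- purrr::map(seq_len(n_phenomena), function(j) {
      cfg <- sim_config(
        mu_true = mu[j], tau2_true = tau2[j], k_published = k[j],
        eta = template$eta, n_range = template$n_range,
        alpha = template$alpha, mlr_mu = mu[j] + template$mlr_offset,
        mlr_n = template$mlr_n
      )
      studies <- simulate_meta(cfg)
      studies$phenomenon_id <- ids[j]
      list(studies = dplyr::relocate(studies, "phenomenon_id"),
           mlr = dplyr::mutate(simulate_mlr(cfg),
                               phenomenon_id = ids[j], .before = 1))
    })
    structure(
      list(
        studies = dplyr::bind_rows(purrr::map(pieces, "studies")),
        mlr = dplyr::bind_rows(purrr::map(pieces, "mlr")),
        truth = tibble::tibble(
          phenomenon_id = ids, mu_true = mu, tau2_true = tau2,
          eta = template$eta, mlr_mu = mu + template$mlr_offset, k = k
        )
      ),
      class = "phenomenon_suite"
    )
  })
}

#' @export
print.phenomenon_suite <- function(x, ...) {
  cat("Synthetic phenomenon suite: ", nrow(x$mlr), " phenomena, ",
      nrow(x$studies), " published studies\n", sep = "")
  print(x$truth, ...)
  invisible(x)
}
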