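test_that("Cochran's Q matches hand evaluation and degenerate cases", {
  expect_equal(
    cochran_q(data.frame(estimate = c(0, 0.5, 1), variance = rep(0.1, 3))),
    5.0
  )
  # identical estimates: zero dispersion regardless of variances
  expect_equal(
    cochran_q(data.frame(estimate = rep(0.3, 4),
                         variance = c(0.1, 0.2, 0.05, 0.4))),
    0
  )
  expect_equal(cochran_q(data.frame(estimate = 0.4, variance = 0.1)), 0)
  expect_error(cochran_q(data.frame(estimate = numeric(), variance = numeric())),
               "at least 1")
})

test_that("input validation rejects malformed study tables", {
  expect_error(validate_studies(data.frame(estimate = 1)), "variance")
  expect_error(validate_studies(data.frame(estimate = 1, variance = 0)),
               "> 0")
  expect_error(validate_studies(data.frame(estimate = Inf, variance = 1)),
               "finite")
  expect_error(
    validate_studies(data.frame(estimate = c(1, 2), variance = c(1, 1),
                                study_label = c("a", "a"))),
    "unique"
  )
})

test_that("tau2 estimators reproduce hand-derived values", {
  d <- data.frame(estimate = c(0, 0.5, 1), variance = rep(0.1, 3))
  # Q = 5, k - 1 = 2, C = 30 - 300/30 = 20 -> (5 - 2)/20
  expect_equal(estimate_tau2(d, "DL"), 0.15)
  # identical estimates -> 0 for every method
  same <- data.frame(estimate = rep(0.2, 5), variance = runif(5, 0.01, 0.1))
  for (m in c("PM", "DL", "REML")) {
    expect_equal(estimate_tau2(same, m), 0, info = m)
  }
  expect_warning(
    out <- estimate_tau2(data.frame(estimate = 0.3, variance = 0.1), "PM"),
    "not identifiable"
  )
  expect_equal(out, 0)
})

test_that("PM and REML agree with brute-force oracles on random datasets", {
  withr::with_seed(401, {
    for (i in 1:100) {
      d <- random_dataset()
      expect_equal(estimate_tau2(d, "DL"),
                   oracle_dl(d$estimate, d$variance), tolerance = 1e-10)
      expect_equal(estimate_tau2(d, "PM"),
                   oracle_pm(d$estimate, d$variance), tolerance = 1e-6)
      reml <- estimate_tau2(d, "REML")
      expect_lt(abs(reml - oracle_reml_grid(d$estimate, d$variance)), 1e-3)
    }
  })
})

test_that("tau2 estimators agree with metafor on a handful of datasets", {
  skip_if_not_installed("metafor")
  withr::with_seed(77, {
    for (i in 1:5) {
      d <- random_dataset(k = 8)
      for (m in c("DL", "PM", "REML")) {
        ref <- metafor::rma(yi = d$estimate, vi = d$variance, method = m)
        expect_equal(estimate_tau2(d, m), as.numeric(ref$tau2),
                     tolerance = 1e-4, info = m)
      }
    }
  })
})

test_that("random-effects fit matches pooled-mean arithmetic and metafor", {
  withr::with_seed(402, {
    d <- random_dataset(k = 5)
    fit <- fit_random_effects(d, tau2_method = "PM")
    expect_equal(fit$mu, oracle_pooled_mean(d$estimate, d$variance, fit$tau2),
                 tolerance = 1e-10)
    skip_if_not_installed("metafor")
    ref <- metafor::rma(yi = d$estimate, vi = d$variance, method = "REML")
    fit2 <- fit_random_effects(d, tau2_method = "REML")
    expect_equal(fit2$mu, as.numeric(ref$beta), tolerance = 1e-4)
    expect_equal(fit2$se_mu, as.numeric(ref$se), tolerance = 1e-4)
  })
})

test_that("fit handles single-study, forced-tau2 and interval contracts", {
  one <- fit_random_effects(data.frame(estimate = 0.5, variance = 0.04))
  expect_equal(one$mu, 0.5)
  expect_equal(one$se_mu, 0.2)
  expect_true(one$low_k)

  two <- fit_random_effects(
    data.frame(estimate = c(0.2, 0.4), variance = c(0.01, 0.01)), tau2 = 0)
  expect_equal(two$mu, 0.3)

  d <- random_dataset(k = 6)
  wz <- fit_random_effects(d, interval_method = "wald_z")
  hk <- fit_random_effects(d, interval_method = "hksj")
  expect_equal(wz$ci_high - wz$mu, 1.959964 * wz$se_mu, tolerance = 1e-6)
  expect_equal(hk$ci_high - hk$mu,
               stats::qt(0.975, df = hk$k - 1) * hk$se_mu, tolerance = 1e-10)
  for (f in list(wz, hk)) {
    expect_true(f$ci_low <= f$mu && f$mu <= f$ci_high)
    expect_gt(f$se_mu, 0)
    expect_gte(f$tau2, 0)
  }
})

test_that("hksj interval matches metafor's Knapp-Hartung fit", {
  skip_if_not_installed("metafor")
  withr::with_seed(403, {
    d <- random_dataset(k = 7)
    fit <- fit_random_effects(d, tau2_method = "REML",
                              interval_method = "hksj")
    ref <- metafor::rma(yi = d$estimate, vi = d$variance, method = "REML",
                        test = "knha")
    expect_equal(fit$ci_low, as.numeric(ref$ci.lb), tolerance = 1e-4)
    expect_equal(fit$ci_high, as.numeric(ref$ci.ub), tolerance = 1e-4)
  })
})

test_that("tau2 is shift-invariant and mu shifts by the constant", {
  withr::with_seed(404, {
    for (i in 1:20) {
      d <- random_dataset()
      shift <- runif(1, -2, 2)
      d2 <- dplyr::mutate(d, estimate = estimate + shift)
      for (m in c("PM", "DL", "REML")) {
        expect_equal(estimate_tau2(d, m), estimate_tau2(d2, m),
                     tolerance = 1e-6, info = m)
      }
      f1 <- fit_random_effects(d)
      f2 <- fit_random_effects(d2)
      expect_equal(f2$mu, f1$mu + shift, tolerance = 1e-6)
    }
  })
})

test_that("pooled mean stays within the estimate range and hits the v->0 limit", {
  withr::with_seed(405, {
    for (i in 1:20) {
      d <- random_dataset()
      f <- fit_random_effects(d)
      expect_gte(f$mu, min(d$estimate))
      expect_lte(f$mu, max(d$estimate))
    }
    # vanishing sampling variances: weights equalize, mu -> unweighted mean
    y <- rnorm(6, 0.4, 0.3)
    tiny <- data.frame(estimate = y, variance = rep(1e-10, 6))
    f <- fit_random_effects(tiny, tau2_method = "DL")
    expect_equal(f$mu, mean(y), tolerance = 1e-4)
  })
})

test_that("the naive estimator recovers the true mean without selection", {
  withr::with_seed(406, {
    est <- replicate(500, {
      d <- simulate_meta(sim_config(mu_true = 0.3, tau2_true = 0.1,
                                    k_published = 40))
      fit_random_effects(d, tau2_method = "DL")$mu
    })
    # MC standard error ~ sqrt(var(muhat)/500); muhat SE ~ sqrt(0.1/40 + E v/40)
    expect_lt(abs(mean(est) - 0.3), 3 * stats::sd(est) / sqrt(500))
  })
})

test_that("tidy and glance views expose the fit", {
  d <- data.frame(estimate = c(0.1, 0.5, 0.3), variance = rep(0.04, 3))
  fit <- fit_random_effects(d)
  td <- tidy(fit)
  expect_equal(td$estimate, fit$mu)
  gl <- glance(fit)
  expect_equal(gl$tau2, fit$tau2)
  expect_equal(gl$k, 3L)
  expect_output(print(fit), "pooled mean")
})
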