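test_that("correlation layer reproduces identity and arithmetic oracles", {
  pairs <- data.frame(ma_estimate = c(0.2, 0.4, 0.6, 0.8),
                      mlr_estimate = c(0.2, 0.4, 0.6, 0.8))
  res <- correlate_estimates(pairs)
  expect_equal(res$r, 1)
  expect_equal(res$slope, 1)
  expect_equal(res$intercept, 0)

  withr::with_seed(801, {
    for (i in 1:30) {
      n <- sample(4:20, 1)
      x <- rnorm(n)
      y <- 0.5 * x + rnorm(n, sd = 0.4)
      res <- correlate_estimates(data.frame(ma_estimate = x,
                                            mlr_estimate = y))
      expect_equal(res$r, oracle_pearson(x, y), tolerance = 1e-12)
      ols <- stats::lm(y ~ x)
      expect_equal(res$slope, unname(coef(ols)[2]), tolerance = 1e-10)
      expect_equal(res$intercept, unname(coef(ols)[1]), tolerance = 1e-10)
      ct <- stats::cor.test(x, y)
      expect_equal(res$p_value, ct$p.value, tolerance = 1e-10)
      expect_equal(c(res$ci_low, res$ci_high),
                   as.numeric(ct$conf.int), tolerance = 1e-10)
    }
  })
})

test_that("correlation input contracts are enforced", {
  expect_error(correlate_estimates(
    data.frame(ma_estimate = c(1, 2), mlr_estimate = c(1, 2))), "At least 3")
  expect_error(correlate_estimates(
    data.frame(ma_estimate = c(1, 1, 1), mlr_estimate = c(1, 2, 3))),
    "zero variance")
  expect_error(correlate_estimates(data.frame(ma_estimate = 1:3)),
               "mlr_estimate")
})

test_that("sensitivity summary applies the filter and the stated arithmetic", {
  tab <- data.frame(
    naive_mu = c(0.4, 0.2, 0.1, 0.5),
    mlr_estimate = c(0.1, 0.15, 0.3, 0.2),
    worst_case_mu = c(0.2, 0.1, 0.05, NA),
    worst_estimable = c(TRUE, TRUE, TRUE, FALSE),
    phat = c(0.2, 0.3, 0.5, 0.1)
  )
  # rows 3 (naive <= MLR) and 4 (not estimable) are excluded
  s <- sensitivity_summary(tab)
  expect_equal(s$n_analyzed, 2L)
  expect_equal(s$mean_naive, 0.3)
  expect_equal(s$mean_worst_case, 0.15)
  expect_equal(s$mean_ratio, 0.5)
  expect_equal(s$ratio_of_means, 0.5)
  expect_equal(s$mean_abs_diff, 0.15)
  expect_equal(s$prop_worst_exceeds_mlr, 0.5)
  expect_equal(s$prop_worst_exceeds_null, 1)
  expect_equal(s$median_phat, median(c(0.2, 0.3, 0.5, 0.1)))
  expect_equal(s$median_phat_included, 0.25)

  # mean-of-ratios and ratio-of-means genuinely differ on uneven pairs
  tab2 <- data.frame(naive_mu = c(0.5, 0.1), mlr_estimate = c(0, 0),
                     worst_case_mu = c(0.1, 0.05),
                     worst_estimable = TRUE, phat = NA_real_)
  s2 <- sensitivity_summary(tab2)
  expect_equal(s2$mean_ratio, mean(c(0.1 / 0.5, 0.05 / 0.1)))
  expect_equal(s2$ratio_of_means, mean(c(0.1, 0.05)) / mean(c(0.5, 0.1)))
  expect_false(isTRUE(all.equal(s2$mean_ratio, s2$ratio_of_means)))

  empty <- sensitivity_summary(
    data.frame(naive_mu = 0.1, mlr_estimate = 0.5, worst_case_mu = 0.05,
               worst_estimable = TRUE, phat = 0.9))
  expect_equal(empty$n_analyzed, 0L)
  expect_true(is.na(empty$mean_naive))
  expect_equal(empty$median_phat, 0.9)
})

test_that("full comparison produces an aligned, deterministic report", {
  suite <- simulate_phenomenon_suite(6, suite_template(eta = 3), seed = 41)
  rep1 <- run_full_comparison(suite, n_boot = 200, seed = 5, eta = c(1, 5))
  rep2 <- run_full_comparison(suite, n_boot = 200, seed = 5, eta = c(1, 5))
  expect_identical(
    jsonlite::serializeJSON(unclass(rep1)),
    jsonlite::serializeJSON(unclass(rep2))
  )
  per <- rep1$per_phenomenon
  expect_equal(nrow(per), 6L)
  expect_identical(per$phenomenon_id, suite$truth$phenomenon_id)
  expect_equal(per$k + 0L, suite$truth$k, ignore_attr = TRUE)
  expect_true(all(per$n_affirmative + per$n_nonaffirmative == per$k))
  # eta = 1 rows of the corrected table equal the naive means
  eta1 <- rep1$corrected[rep1$corrected$eta == 1, ]
  expect_equal(eta1$corrected_mu, per$naive_mu, tolerance = 1e-10)
  # report statistics are invariant to phenomenon ordering
  shuffled_idx <- c(4, 2, 6, 1, 5, 3)
  ids <- unique(suite$studies$phenomenon_id)[shuffled_idx]
  studies_shuffled <- dplyr::arrange(
    suite$studies, match(phenomenon_id, ids))
  rep3 <- run_full_comparison(studies_shuffled, suite$mlr,
                              n_boot = 200, seed = 5)
  expect_equal(sort(rep3$per_phenomenon$naive_mu), sort(per$naive_mu))
  expect_equal(rep3$correlation$r, rep1$correlation$r, tolerance = 1e-12)
  s3 <- rep3$summary
  s1 <- rep1$summary
  expect_equal(s3$mean_naive, s1$mean_naive)
  expect_equal(s3$median_phat, s1$median_phat)
})

test_that("comparison handles missing correlation and propagates context", {
  suite <- simulate_phenomenon_suite(2, suite_template(), seed = 43)
  one <- list(studies = suite$studies[suite$studies$phenomenon_id ==
                                        suite$truth$phenomenon_id[1], ],
              mlr = suite$mlr[1, ])
  rep1 <- run_full_comparison(one$studies, one$mlr, n_boot = 200, seed = 1)
  expect_null(rep1$correlation)
  expect_equal(nrow(rep1$per_phenomenon), 1L)
  expect_true(all(c("naive_mu", "phat", "worst_case_mu") %in%
                    names(rep1$per_phenomenon)))
  gl <- glance(rep1)
  expect_true(is.na(gl$r))

  expect_error(run_full_comparison(suite$studies, suite$mlr[1, ],
                                   n_boot = 200, seed = 1),
               "No MLR estimate")
})

test_that("a no-bias world concentrates near no discrepancy", {
  suite <- simulate_phenomenon_suite(
    10, suite_template(eta = 1, mlr_offset = 0, mu_mean = 0.5, mu_sd = 0.3,
                       k_range = c(25, 40), mlr_n = 2e5), seed = 44)
  rep1 <- run_full_comparison(suite, n_boot = 200, seed = 6)
  s <- rep1$summary
  # Even without publication bias the worst case is conservative (it
  # conditions on non-significance), so mean_ratio stays well below 1;
  # the no-discrepancy signal lives in the slope and the null exceedance.
  if (s$n_analyzed >= 3) {
    expect_gt(s$prop_worst_exceeds_null, 0.5)
  }
  expect_gt(rep1$correlation$r, 0.5)
  expect_gt(rep1$correlation$slope, 0.6)
  expect_lt(rep1$correlation$slope, 1.4)
})

test_that("plot functions return ggplot objects", {
  suite <- simulate_phenomenon_suite(4, suite_template(), seed = 45)
  rep1 <- run_full_comparison(suite, n_boot = 200, seed = 7)
  expect_s3_class(plot_estimate_scatter(rep1), "ggplot")
  expect_s3_class(plot_sensitivity_forest(rep1), "ggplot")
  expect_s3_class(ggplot2::autoplot(rep1), "ggplot")
  expect_output(print(rep1), "correlation")
})
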