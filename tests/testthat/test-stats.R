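test_that("2x2 diagnostics reproduce the reconstructed cohort tables", {
  # CPI >= 20% table reconstructed from sensitivity 70%, specificity 66%,
  # 27 events among 80 patients
  m <- two_by_two_metrics(19, 18, 8, 35)
  expect_equal(round(m$odds_ratio, 2), 4.62)
  expect_equal(m$accuracy, 67.5)
  expect_equal(m$ppv, 100 * 19 / 37, tolerance = 1e-9)
  expect_lt(abs(m$ppv - 51), 0.5)
  expect_equal(m$npv, 100 * 35 / 43, tolerance = 1e-9)
  expect_false(m$continuity_corrected)
  expect_lt(m$fisher_p, 0.05)

  # CPMax >= 0.40 MPa table from stratum incidences 53.7% / 12.8%
  m2 <- two_by_two_metrics(22, 19, 5, 34)
  expect_equal(round(m2$odds_ratio, 2), 7.87)

  # symmetric table carries no association
  m3 <- two_by_two_metrics(10, 10, 10, 10)
  expect_equal(m3$odds_ratio, 1.0)
  expect_equal(m3$accuracy, 50)

  # zero cell triggers the flagged continuity correction
  m4 <- two_by_two_metrics(5, 0, 3, 12)
  expect_true(m4$continuity_corrected)
  expect_true(is.finite(m4$odds_ratio))
  expect_error(two_by_two_metrics(-1, 2, 3, 4), "invalid-parameter")
})

test_that("empirical AUC behaves at the separation limits and matches pROC", {
  r <- roc_auc(c(1, 2, 3, 11, 12, 13), c(F, F, F, T, T, T))
  expect_equal(r$auc, 1.0)

  set.seed(1)
  x <- rnorm(4000); y <- rep(c(TRUE, FALSE), 2000)
  r0 <- roc_auc(x, y)
  expect_lt(abs(r0$auc - 0.5), 0.03)
  expect_true(r0$ci_low <= r0$auc && r0$auc <= r0$ci_high)

  skip_if_not_installed("pROC")
  set.seed(2)
  sc <- c(rnorm(300, 1), rnorm(500, 0))
  lb <- c(rep(TRUE, 300), rep(FALSE, 500))
  mine <- roc_auc(sc, lb)
  ref <- pROC::roc(lb, sc, quiet = TRUE, direction = "<")
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(mine$ci_low, ci[1], tolerance = 1e-9)
  expect_equal(mine$ci_high, ci[3], tolerance = 1e-9)

  expect_error(roc_auc(1:5, rep(TRUE, 5)), "degenerate-input")
})

test_that("binormal closed form matches the printed group statistics", {
  expect_equal(binormal_auc(28.3, 15.8, 15.6, 11.2), pnorm(12.7 / sqrt(15.8^2 + 11.2^2)))
  expect_equal(round(binormal_auc(28.3, 15.8, 15.6, 11.2), 3), 0.744)
  expect_equal(round(binormal_auc(0.51, 0.20, 0.36, 0.24), 3), 0.684)
  expect_equal(binormal_auc(5, 1, 5, 2), 0.5)
  expect_error(binormal_auc(1, 0, 2, 0), "undefined")

  # empirical AUC converges to the binormal value under Gaussian sampling
  set.seed(4)
  n <- 50000
  sc <- c(rnorm(n, 28.3, 15.8), rnorm(n, 15.6, 11.2))
  lb <- rep(c(TRUE, FALSE), each = n)
  expect_lt(abs(roc_auc(sc, lb)$auc - binormal_auc(28.3, 15.8, 15.6, 11.2)),
            0.01)
})

test_that("the Youden-optimal cutoff maximizes sensitivity + specificity - 1", {
  # perfect separation: J = 1 at a threshold between the classes
  oc <- optimal_cutoff(c(1, 2, 3, 11, 12, 13), c(F, F, F, T, T, T))
  expect_equal(oc$youden_j, 1)
  expect_true(oc$threshold > 3 && oc$threshold <= 11)

  # constant scores: no discrimination
  oc0 <- optimal_cutoff(rep(2, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(oc0$youden_j, 0)

  # the reconstructed CPI operating point has J = 0.364
  expect_equal(19 / 27 + 35 / 53 - 1, 0.364, tolerance = 0.001)

  # exhaustive check against a brute-force scan on random data
  set.seed(9)
  sc <- sample(1:20, 60, replace = TRUE)
  lb <- runif(60) < 0.4
  oc2 <- optimal_cutoff(sc, lb)
  brute <- sapply(sort(unique(sc)), function(t) {
    mean(sc[lb] >= t) + mean(sc[!lb] < t) - 1
  })
  expect_equal(oc2$youden_j, max(brute))
})

test_that("logistic regression agrees with the 2x2 odds ratio and handles separation", {
  # 80 subjects expanded from the reconstructed CPI table
  flag <- c(rep(TRUE, 19 + 18), rep(FALSE, 8 + 35))
  out <- c(rep(TRUE, 19), rep(FALSE, 18), rep(TRUE, 8), rep(FALSE, 35))
  fit <- logistic_fit(out, data.frame(cpi_ge_20 = flag))
  expect_equal(round(fit$or[1], 2), 4.62)
  expect_false(attr(fit, "separation"))

  # equivalence property on random non-degenerate tables
  set.seed(12)
  for (i in 1:10) {
    cells <- rpois(4, 15) + 1
    f2 <- c(rep(TRUE, cells[1] + cells[2]), rep(FALSE, cells[3] + cells[4]))
    o2 <- c(rep(TRUE, cells[1]), rep(FALSE, cells[2]),
            rep(TRUE, cells[3]), rep(FALSE, cells[4]))
    expect_equal(logistic_fit(o2, data.frame(x = f2))$or[1],
                 two_by_two_metrics(cells[1], cells[2], cells[3],
                                    cells[4])$odds_ratio,
                 tolerance = 1e-4)
  }

  # a null predictor at large n has OR near 1
  set.seed(13)
  n <- 5000
  fit0 <- logistic_fit(runif(n) < 0.3, data.frame(x = runif(n) < 0.5))
  expect_lt(abs(fit0$or[1] - 1), 0.2)

  # three-predictor multivariate fit reports three adjusted ORs
  co <- generate_statistical_cohort(2000, seed = 14)
  fit3 <- logistic_fit(co$outcome_mcd,
                       data.frame(cpi_ge_20 = co$cpi >= 20,
                                  cpmax_ge_040 = co$cpmax >= 0.40,
                                  depth_ge_5 = co$implantation_depth >= 5))
  expect_equal(nrow(fit3), 3)
  expect_true(all(is.finite(fit3$or)))

  # complete separation is flagged
  sep <- logistic_fit(c(rep(TRUE, 10), rep(FALSE, 10)),
                      data.frame(x = c(rep(1, 10), rep(0, 10))))
  expect_true(attr(sep, "separation"))

  expect_error(logistic_fit(rep(TRUE, 10), data.frame(x = 1:10)),
               "degenerate-input")
})

test_that("survival analysis recovers a known rate ratio and degenerates cleanly", {
  set.seed(21)
  n <- 5000
  grp <- rep(c(FALSE, TRUE), each = n / 2)
  # average the estimate over a few replicates so the Monte-Carlo error of
  # the recovery check is well inside the 10% band
  hrs <- replicate(3, {
    t_death <- rexp(n, ifelse(grp, 0.3, 0.1))
    survival_analysis(pmin(t_death, 5), t_death <= 5, grp)$hr
  })
  expect_gt(exp(mean(log(hrs))), 2.7)
  expect_lt(exp(mean(log(hrs))), 3.3)
  t_death <- rexp(n, ifelse(grp, 0.3, 0.1))
  sv <- survival_analysis(pmin(t_death, 5), t_death <= 5, grp)
  expect_lt(sv$logrank_p, 1e-10)
  expect_true(sv$ci_low < sv$hr && sv$hr < sv$ci_high)

  # identical groups: null hazard ratio
  set.seed(22)
  t0 <- rexp(n, 0.2)
  sv0 <- survival_analysis(pmin(t0, 5), t0 <= 5, rep(c(0, 1), n / 2))
  expect_lt(abs(sv0$hr - 1), 0.15)

  expect_error(survival_analysis(c(-1, 2), c(TRUE, FALSE), c(0, 1)),
               "invalid-parameter")
  expect_error(survival_analysis(c(1, 2), c(FALSE, FALSE), c(0, 1)),
               "undefined")
})

test_that("group tests are caller-explicit with calibrated behavior", {
  # identical groups: t statistic 0, p = 1
  x <- c(1, 2, 3, 4, 1, 2, 3, 4)
  g <- rep(c("a", "b"), each = 4)
  tt <- group_tests(x, g, test = "t")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)

  # the printed CPI effect size is detectable at the cohort's group sizes
  set.seed(31)
  rej <- mean(replicate(200, {
    v <- c(rnorm(27, 28.3, 15.8), rnorm(53, 15.6, 11.2))
    group_tests(v, rep(c("mcd", "none"), c(27, 53)), test = "t")$p_value < 0.05
  }))
  expect_gt(rej, 0.5)

  # ANOVA type-I calibration under the null
  set.seed(32)
  p_null <- replicate(300, {
    v <- rnorm(48)
    group_tests(v, rep(letters[1:4], each = 12), test = "anova")$p_value
  })
  expect_lt(abs(mean(p_null < 0.05) - 0.05), 0.05)

  mw <- group_tests(x, g, test = "mannwhitney")
  expect_equal(mw$p_value, 1)
  fi <- group_tests(rep(c("y", "n"), 10), rep(c("a", "b"), each = 10),
                    test = "fisher")
  expect_true(fi$p_value <= 1)
  expect_error(group_tests(x, rep("a", 8), test = "t"), "degenerate-input")
})
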