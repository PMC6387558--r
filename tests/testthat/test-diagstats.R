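test_that("Clopper-Pearson intervals match binomial tail inversion", {
  ## closed form at the boundary: lower bound of x = n is (a/2)^(1/n)
  ci <- clopper_pearson(64, 64)
  expect_equal(ci[["lower"]], 0.025^(1 / 64))
  expect_equal(ci[["upper"]], 1)
  expect_equal(clopper_pearson(0, 10)[["lower"]], 0)

  ## brute-force search over binomial tail probabilities
  for (case in list(c(64, 72), c(57, 60), c(31, 36), c(7, 19))) {
    x <- case[1]; n <- case[2]
    ci <- clopper_pearson(x, n)
    grid <- seq(1e-5, 1 - 1e-5, by = 1e-5)
    lo <- grid[which(pbinom(x - 1, n, grid, lower.tail = FALSE) >= 0.025)[1]]
    hi <- grid[rev(which(pbinom(x, n, grid) >= 0.025))[1]]
    expect_lt(abs(ci[["lower"]] - lo), 2e-5)
    expect_lt(abs(ci[["upper"]] - hi), 2e-5)
    expect_equal(unname(ci), binom.test(x, n)$conf.int[1:2], tolerance = 1e-12)
  }
})

test_that("pairwise confusion excludes third-pattern labels", {
  truth <- c(rep("DLB", 72), rep("PD", 36))
  labels <- c(rep("DLB_LIKE", 64), rep("AD_LIKE", 8),
              rep("DLB_LIKE", 5), rep("PD_LIKE", 31))
  cf <- pairwise_confusion(labels, truth, "DLB", "PD")
  expect_equal(unclass(cf)[c("tp", "fn", "tn", "fp")],
               list(tp = 64L, fn = 0L, tn = 31L, fp = 5L))
  ## without third-pattern labels this is the naive 2-class confusion
  t2 <- c("DLB", "DLB", "ADD", "ADD")
  l2 <- c("DLB_LIKE", "AD_LIKE", "AD_LIKE", "DLB_LIKE")
  cf2 <- pairwise_confusion(l2, t2, "DLB", "ADD")
  expect_equal(unclass(cf2)[c("tp", "fn", "tn", "fp")],
               list(tp = 1L, fn = 1L, tn = 1L, fp = 1L))
  expect_error(pairwise_confusion(rep("PD_LIKE", 4), t2, "DLB", "ADD"), "empty class")
})

test_that("performance point estimates and intervals sit inside [0,1] coherently", {
  p <- performance(confusion2x2(64, 8, 57, 3))
  expect_equal(p$sensitivity, 64 / 72)
  expect_equal(p$specificity, 57 / 60)
  expect_equal(p$accuracy, 121 / 132)
  expect_true(p$sensitivity >= p$sensitivity_ci[1] && p$sensitivity <= p$sensitivity_ci[2])
  expect_true(all(unlist(p[c("sensitivity_ci", "specificity_ci", "accuracy_ci")]) >= 0))
  expect_true(all(unlist(p[c("sensitivity_ci", "specificity_ci", "accuracy_ci")]) <= 1))
})

test_that("agreement and relative gain arithmetic", {
  a <- agreement_and_gain(44, 64, 72)
  expect_equal(round(100 * a$prop_entry, 1), 61.1)
  expect_equal(round(100 * a$prop_test, 2), 88.89)
  expect_equal(round(100 * a$relative_gain, 1), 45.5)
  expect_equal(agreement_and_gain(20, 20, 50)$relative_gain, 0)
  expect_equal(agreement_and_gain(10, 20, 100)$relative_gain, 1)
  expect_error(agreement_and_gain(0, 5, 10), "undefined")
})

test_that("Pearson chi-square is uncorrected and permutation-invariant", {
  t1 <- rbind(c(29, 2), c(26, 15))
  expect_equal(round(pearson_chi2(t1)$statistic, 3), 8.887)
  expect_equal(pearson_chi2(t1)$statistic,
               unname(chisq.test(t1, correct = FALSE)$statistic))
  expect_equal(pearson_chi2(t1)$statistic, pearson_chi2(t1[2:1, ])$statistic)
  expect_equal(pearson_chi2(t1)$statistic, pearson_chi2(t1[, 2:1])$statistic)
  expect_equal(pearson_chi2(rbind(c(10, 20), c(5, 10)))$statistic, 0)
  expect_error(pearson_chi2(rbind(c(0, 0), c(1, 2))), "zero margin")
})

test_that("McNemar matches its closed forms and base R", {
  expect_equal(mcnemar_chi2(10, 10)$statistic, 0.05)
  expect_equal(round(mcnemar_chi2(5, 25)$statistic, 3), 12.033)
  expect_equal(mcnemar_chi2(5, 25)$statistic, mcnemar_chi2(25, 5)$statistic)
  tab <- rbind(c(30, 5), c(25, 12))
  expect_equal(mcnemar_chi2(5, 25)$statistic,
               unname(mcnemar.test(tab)$statistic))
  expect_equal(mcnemar_chi2(4, 8, continuity_corrected = FALSE)$statistic, 16 / 12)
  expect_error(mcnemar_chi2(0, 0), "discordant")
})

test_that("DeLong AUCs, variance and null distribution behave", {
  set.seed(101)
  y <- rep(c(TRUE, FALSE), each = 15)
  s1 <- rnorm(30) + y; s2 <- 0.6 * s1 + rnorm(30)
  d <- delong_paired(s1, s2, y)
  expect_equal(d$auc1, pair_count_auc(s1[y], s1[!y]))
  expect_equal(d$auc2, pair_count_auc(s2[y], s2[!y]))
  expect_equal(delong_paired(s1, s1, y)$Z, 0)
  expect_equal(delong_paired(s1, s1, y)$p, 1)
  skip_if_not_installed("pROC")
  rt <- pROC::roc.test(pROC::roc(y, s1, quiet = TRUE), pROC::roc(y, s2, quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(d$Z, unname(rt$statistic), tolerance = 1e-10)
  expect_equal(d$p, rt$p.value, tolerance = 1e-10)
})

test_that("the DeLong variance agrees with the bootstrap and its null Z is standard normal", {
  set.seed(202)
  y <- rep(c(TRUE, FALSE), each = 15)
  s <- rnorm(30) + 0.8 * y
  ## single-AUC variance from the structural components
  xs <- s[y]; ys <- s[!y]
  psi <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  v_structural <- var(rowMeans(psi)) / 15 + var(colMeans(psi)) / 15
  boot <- replicate(2000, {
    i <- sample(30, replace = TRUE)
    yy <- y[i]
    if (!any(yy) || all(yy)) NA_real_ else pair_count_auc(s[i][yy], s[i][!yy])
  })
  expect_lt(abs(var(boot, na.rm = TRUE) - v_structural) / v_structural, 0.2)

  set.seed(303)
  z <- replicate(500, {
    yy <- rep(c(TRUE, FALSE), each = 12)
    delong_paired(rnorm(24), rnorm(24), yy)$Z
  })
  expect_gt(suppressWarnings(ks.test(z, "pnorm"))$p.value, 0.01)
})

test_that("Welch's t agrees with base R and the published subgroup summary is significant", {
  set.seed(7)
  x <- rnorm(20, 1); y <- rnorm(25)
  w <- welch_t(x, y)
  tt <- t.test(x, y)
  expect_equal(w$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(w$p, tt$p.value, tolerance = 1e-12)
  expect_equal(welch_t(x, x)$t, 0)
  expect_equal(welch_t(x, x)$p, 1)
  ws <- welch_t_summary(mean(x), sd(x), 20, mean(y), sd(y), 25)
  expect_equal(ws$t, w$t, tolerance = 1e-10)
  expect_lte(welch_t_summary(19.96, 4.39, 41, 16.24, 4.87, 31)$p, 0.01)
})
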