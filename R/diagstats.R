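#' Round half-up to two decimals
#'
#' Reporting convention for proportions and confidence limits (matches how
#' clinical performance tables are usually printed; base `round()` rounds
#' half to even).
#'
#' @param x numeric.
#' @param digits decimal places (default 2).
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Beta-quantile form of the exact interval: lower
#' `qbeta(a/2, x, n-x+1)` (0 when `x = 0`), upper `qbeta(1-a/2, x+1, n-x)`
#' (1 when `x = n`).
#'
#' @param x successes.
#' @param n trials.
#' @param conf confidence level (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  stopifnot(x >= 0, n >= 1, x <= n)
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lo, upper = hi)
}

#' 2x2 confusion table for a pairwise cohort comparison
#'
#' Restricts to subjects of the two cohorts whose voted label is A-like or
#' B-like; subjects carrying a third pattern label are EXCLUDED from the
#' comparison (they answer a different differential). Then `tp` = cohort-A
#' subjects labelled A-like, `fn` = A labelled B-like, `tn` = B labelled
#' B-like, `fp` = B labelled A-like.
#'
#' @param labels pattern labels (e.g. `"DLB_LIKE"`).
#' @param truth cohort names (e.g. `"DLB"`).
#' @param disease_a,disease_b cohort names of the positive and comparison class.
#' @param label_map cohort name to pattern label.
#' @return list of class `confusion2x2` with `tp`, `fn`, `tn`, `fp`.
#' @export
pairwise_confusion <- function(labels, truth, disease_a, disease_b,
                               label_map = c(DLB = "DLB_LIKE", ADD = "AD_LIKE",
                                             PCA = "PCA_LIKE", PD = "PD_LIKE")) {
  stopifnot(length(labels) == length(truth))
  la <- label_map[[disease_a]]; lb <- label_map[[disease_b]]
  keep <- truth %in% c(disease_a, disease_b) & labels %in% c(la, lb)
  labels <- labels[keep]; truth <- truth[keep]
  cf <- confusion2x2(tp = sum(truth == disease_a & labels == la),
                     fn = sum(truth == disease_a & labels == lb),
                     tn = sum(truth == disease_b & labels == lb),
                     fp = sum(truth == disease_b & labels == la))
  cf
}

#' Construct a 2x2 confusion object
#'
#' @param tp,fn,tn,fp non-negative counts; each class must retain at least
#'   one subject.
#' @return list of class `confusion2x2`.
#' @export
confusion2x2 <- function(tp, fn, tn, fp) {
  tp <- unname(tp); fn <- unname(fn); tn <- unname(tn); fp <- unname(fp)
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  if (tp + fn == 0 || tn + fp == 0)
    stop("empty class after exclusion: cannot compute performance")
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp), class = "confusion2x2")
}

#' Sensitivity, specificity and accuracy with exact intervals
#'
#' Point estimates with exact 95% Clopper-Pearson confidence intervals, plus
#' the two-decimal rounded report values (half-up).
#'
#' @param confusion a `confusion2x2`.
#' @param conf confidence level.
#' @return list of class `performance_result` with `sensitivity`,
#'   `specificity`, `accuracy`, their `_ci` vectors, and `rounded` (a named
#'   vector of all nine report values).
#' @export
performance <- function(confusion, conf = 0.95) {
  stopifnot(inherits(confusion, "confusion2x2"))
  with(confusion, {
    n <- tp + fn + tn + fp
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    acc <- (tp + tn) / n
    sci <- clopper_pearson(tp, tp + fn, conf)
    pci <- clopper_pearson(tn, tn + fp, conf)
    aci <- clopper_pearson(tp + tn, n, conf)
    rounded <- round_half_up(c(sens = sens, sens_lo = sci[1], sens_hi = sci[2],
                               spec = spec, spec_lo = pci[1], spec_hi = pci[2],
                               acc = acc, acc_lo = aci[1], acc_hi = aci[2]))
    names(rounded) <- c("sens", "sens_lo", "sens_hi", "spec", "spec_lo",
                        "spec_hi", "acc", "acc_lo", "acc_hi")
    structure(list(sensitivity = sens, sensitivity_ci = sci,
                   specificity = spec, specificity_ci = pci,
                   accuracy = acc, accuracy_ci = aci,
                   n = n, rounded = rounded), class = "performance_result")
  })
}

#' Agreement with the diagnostic reference and relative gain
#'
#' Proportions correct at clinical entry and by the imaging classification,
#' and the relative gain `(correct_by_test - correct_at_entry) /
#' correct_at_entry`.
#'
#' @param correct_at_entry,correct_by_test counts of correct classifications.
#' @param n cohort size.
#' @return list with `prop_entry`, `prop_test`, `relative_gain` (proportions).
#' @export
agreement_and_gain <- function(correct_at_entry, correct_by_test, n) {
  stopifnot(correct_at_entry >= 0, correct_by_test >= 0,
            correct_at_entry <= n, correct_by_test <= n)
  if (correct_at_entry == 0) stop("relative gain undefined: zero correct at entry")
  list(prop_entry = correct_at_entry / n,
       prop_test = correct_by_test / n,
       relative_gain = (correct_by_test - correct_at_entry) / correct_at_entry)
}

#' Pearson chi-square test (uncorrected)
#'
#' The uncorrected Pearson statistic; for a 2x2 table this equals
#' `N (ad - bc)^2 / (r1 r2 c1 c2)`. No Yates continuity correction.
#'
#' @param tab matrix of non-negative counts with positive margins.
#' @return list with `statistic`, `df`, `p`.
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin")
  e <- outer(rs, cs) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Chi-square from subgroup rates
#'
#' Reconstructs 2x2 counts from per-subgroup event rates by rounding
#' `rate * n` to the nearest integer, then applies the uncorrected Pearson
#' test — the form needed when only percentages and group sizes are reported.
#'
#' @param rate1,n1 event rate and size of the first subgroup.
#' @param rate2,n2 event rate and size of the second subgroup.
#' @return as [pearson_chi2()], plus the reconstructed `table`.
#' @export
chi2_from_rates <- function(rate1, n1, rate2, n2) {
  a <- round(rate1 * n1); b <- round(rate2 * n2)
  tab <- rbind(c(a, n1 - a), c(b, n2 - b))
  out <- pearson_chi2(tab)
  out$table <- tab
  out
}

#' McNemar test for paired proportions
#'
#' From the discordant-pair counts `b` and `c`:
#' `(|b - c| - 1)^2 / (b + c)` with continuity correction (the default), or
#' `(b - c)^2 / (b + c)` without; p from chi-square with 1 df.
#'
#' @param b,c discordant counts (`b + c > 0`).
#' @param continuity_corrected apply the continuity correction.
#' @return list with `statistic`, `p`.
#' @export
mcnemar_chi2 <- function(b, c, continuity_corrected = TRUE) {
  b <- unname(b); c <- unname(c)
  if (b + c == 0) stop("no discordant pairs")
  stat <- if (continuity_corrected) (abs(b - c) - 1)^2 / (b + c) else (b - c)^2 / (b + c)
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' DeLong test for two paired AUCs
#'
#' Nonparametric comparison of two correlated ROC areas measured on the same
#' subjects. AUCs use the Mann-Whitney identity; the variance of their
#' difference uses the DeLong structural components (per-positive and
#' per-negative placement values). Degenerate variance (e.g. identical score
#' vectors) returns `Z = 0`, `p = 1` by convention.
#'
#' @param scores1,scores2 two score vectors on the same subjects.
#' @param binary_truth logical (or 0/1) vector; `TRUE` = positive class.
#' @return list with `auc1`, `auc2`, `Z`, `p`.
#' @export
delong_paired <- function(scores1, scores2, binary_truth) {
  y <- as.logical(binary_truth)
  stopifnot(length(scores1) == length(y), length(scores2) == length(y))
  if (!any(y) || all(y)) stop("both classes must be present")
  comp <- function(s) {
    xs <- s[y]; ys <- s[!y]
    psi <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
    list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
  }
  c1 <- comp(scores1); c2 <- comp(scores2)
  m <- sum(y); n <- sum(!y)
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (!is.finite(v) || v <= 0) {
    z <- 0; p <- 1
  } else {
    z <- (c1$auc - c2$auc) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc1 = c1$auc, auc2 = c2$auc, Z = z, p = p)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t from raw samples; see [welch_t_summary()] for the
#' summary-statistics form the two share.
#'
#' @param x,y numeric samples (each n >= 2).
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  welch_t_summary(mean(x), stats::sd(x), length(x),
                  mean(y), stats::sd(y), length(y))
}

#' Welch's t-test from group summaries
#'
#' @param m1,s1,n1 mean, sd and size of group 1.
#' @param m2,s2,n2 mean, sd and size of group 2.
#' @return list with `t`, `df` (Welch-Satterthwaite), `p` (two-sided).
#' @export
welch_t_summary <- function(m1, s1, n1, m2, s2, n2) {
  m1 <- unname(m1); s1 <- unname(s1); n1 <- unname(n1)
  m2 <- unname(m2); s2 <- unname(s2); n2 <- unname(n2)
  stopifnot(n1 >= 2, n2 >= 2)
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  if (v1 + v2 == 0) stop("zero variance in both groups")
  tt <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}
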