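#' @name tmap
#' @title Voxel-wise hypometabolism t-maps against a normative database
#' @description
#' Single-subject and group t-maps are mass-univariate ordinary least squares
#' fits of uptake on `[intercept, group indicator, age]`, computed at every
#' in-mask voxel. The sign convention is hypometabolism-positive: `t > 0`
#' means the tested subject (or group) has LOWER uptake than the controls.
NULL

#' Stack control scans into a subjects-by-voxels matrix
#'
#' Precomputing this matrix once and passing it (with `ages`) to
#' [fit_subject_tmap()] avoids re-extracting the control database for every
#' test subject.
#'
#' @param controls list of `subject_scan`s (or 3-D arrays).
#' @param mask logical analysis mask.
#' @return numeric matrix, one row per control, one column per in-mask voxel.
#' @export
control_matrix <- function(controls, mask) {
  .control_matrix(controls, mask)
}

## stack scans (or a prebuilt N x V matrix) into the subjects-by-voxels
## response used by the voxel-wise GLM
.control_matrix <- function(controls, mask) {
  if (is.matrix(controls)) return(controls)
  t(vapply(controls, function(s) {
    v <- if (inherits(s, "subject_scan")) s$volume else s
    v[mask]
  }, numeric(sum(mask))))
}

.scan_ages <- function(scans) {
  vapply(scans, function(s) if (inherits(s, "subject_scan")) s$age else NA_real_,
         numeric(1))
}

## per-voxel OLS t statistics for the group-indicator coefficient (negated so
## reduced uptake is positive); Y is subjects x voxels
.tstat_lm <- function(Y, X) {
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient design (e.g. all ages equal while the age covariate is requested)")
  C <- chol2inv(chol(crossprod(X)))
  B <- C %*% crossprod(X, Y)
  resid <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  s2 <- colSums(resid^2) / df
  ## exact fits leave only floating-point dust in the residuals; treat both
  ## the coefficient and its error as zero below the accumulation scale
  scale_col <- pmax(colMeans(abs(Y)), 1e-300)
  tiny <- 1e-10 * scale_col
  b <- B[2L, ]
  b[abs(b) < tiny] <- 0
  se <- sqrt(s2 * C[2L, 2L])
  zero_var <- se < tiny
  tt <- numeric(length(b))
  ok <- !zero_var
  tt[ok] <- -b[ok] / se[ok]
  tt[zero_var] <- ifelse(b[zero_var] == 0, 0, -sign(b[zero_var]) * Inf)
  list(t = tt, df = df)
}

.make_tmap <- function(tvals, df, mask, n_controls, n_test, use_age) {
  tvol <- array(NA_real_, dim(mask))
  tvol[mask] <- tvals
  structure(list(t = tvol, df = df, mask = mask, n_controls = n_controls,
                 n_test = n_test, use_age = use_age,
                 alpha = NA_real_, threshold = NA_real_,
                 fwe_method = "bonferroni"), class = "tmap")
}

#' Single-subject hypometabolism t-map
#'
#' Fits, at every in-mask voxel, uptake on `[intercept, patient indicator,
#' age]` over the `N` controls plus the one test subject, and returns the
#' negated indicator t statistic so hypometabolism is positive. Degrees of
#' freedom are `(N + 1) - 3` with the age covariate, `(N + 1) - 2` without.
#'
#' @param subject a preprocessed `subject_scan`.
#' @param controls list of preprocessed control `subject_scan`s (>= 10), or a
#'   prebuilt `N x V` matrix of in-mask control values (then `ages` must give
#'   the control ages).
#' @param mask logical analysis mask.
#' @param ages control ages; taken from the scans when `controls` is a list.
#' @param use_age include age as nuisance covariate (default TRUE).
#' @return a `tmap` object: t volume (NA outside the mask), `df`, `mask`,
#'   design description, and (once thresholded) `alpha`/`threshold`.
#' @export
fit_subject_tmap <- function(subject, controls, mask, ages = NULL, use_age = TRUE) {
  cm <- .control_matrix(controls, mask)
  if (nrow(cm) < 10) stop("need at least 10 controls")
  if (is.null(ages)) ages <- .scan_ages(controls)
  if (use_age && (length(ages) != nrow(cm) || anyNA(ages)))
    stop("ages must be supplied for all control subjects")
  svol <- if (inherits(subject, "subject_scan")) subject$volume else subject
  if (!identical(dim(svol), dim(mask)))
    stop(sprintf("patient grid (%s) does not match mask grid (%s)",
                 paste(dim(svol), collapse = "x"), paste(dim(mask), collapse = "x")))
  sage <- if (inherits(subject, "subject_scan")) subject$age else NA_real_
  if (use_age && !is.finite(sage)) stop("test subject age is required")
  Y <- rbind(cm, svol[mask])
  ind <- c(rep(0, nrow(cm)), 1)
  X <- if (use_age) cbind(1, ind, c(ages, sage)) else cbind(1, ind)
  fit <- .tstat_lm(Y, X)
  .make_tmap(fit$t, fit$df, mask, nrow(cm), 1L, use_age)
}

#' Group hypometabolism t-map
#'
#' As [fit_subject_tmap()] with the indicator set for all patients; degrees
#' of freedom are `(Np + N) - 3` with the age covariate.
#'
#' @param patients list of preprocessed patient `subject_scan`s.
#' @inheritParams fit_subject_tmap
#' @return a `tmap`.
#' @export
fit_group_tmap <- function(patients, controls, mask, ages = NULL, use_age = TRUE) {
  cm <- .control_matrix(controls, mask)
  if (nrow(cm) < 10) stop("need at least 10 controls")
  if (is.null(ages)) ages <- .scan_ages(controls)
  pm <- .control_matrix(patients, mask)
  pages <- .scan_ages(patients)
  Y <- rbind(cm, pm)
  ind <- c(rep(0, nrow(cm)), rep(1, nrow(pm)))
  X <- if (use_age) cbind(1, ind, c(ages, pages)) else cbind(1, ind)
  fit <- .tstat_lm(Y, X)
  .make_tmap(fit$t, fit$df, mask, nrow(cm), nrow(pm), use_age)
}

#' Bonferroni familywise-error threshold for a t-map
#'
#' The voxel-level FWE threshold at level `alpha` over the `V` in-mask voxels
#' is the upper-tail Student quantile at `alpha / V` with the map's degrees
#' of freedom. Bonferroni is conservative but exactly implementable; the
#' method tag is recorded on the returned map.
#'
#' @param tmap a `tmap`.
#' @param alpha familywise error level in (0, 1).
#' @return the `tmap` with `alpha` and `threshold` filled in.
#' @seealso [bonferroni_threshold()] for the bare quantile.
#' @export
fwe_threshold <- function(tmap, alpha = 0.05) {
  stopifnot(inherits(tmap, "tmap"))
  tmap$alpha <- alpha
  tmap$threshold <- bonferroni_threshold(alpha, sum(tmap$mask), tmap$df)
  tmap
}

#' Bonferroni-corrected Student threshold
#'
#' @param alpha familywise error level in (0, 1).
#' @param V number of tests (in-mask voxels).
#' @param df degrees of freedom (> 0).
#' @return upper-tail Student quantile at `alpha / V`.
#' @export
bonferroni_threshold <- function(alpha, V, df) {
  stopifnot(alpha > 0, alpha < 1, V >= 1)
  if (df <= 0) stop("degrees of freedom must be positive")
  stats::qt(1 - alpha / V, df)
}
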