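#' Per-region suprathreshold fractions
#'
#' For every analysis ROI and rule composite, the fraction of its voxels that
#' are suprathreshold within a surviving cluster. These continuous fractions
#' are the raw material for the involvement flags and the pattern rules.
#'
#' @param clusters a `cluster_set`.
#' @param atlas a `dlb_atlas`.
#' @return named numeric vector (14 ROIs followed by the composites).
#' @export
roi_fractions <- function(clusters, atlas) {
  stopifnot(inherits(clusters, "cluster_set"), inherits(atlas, "dlb_atlas"))
  supra <- clusters$labels > 0L
  regions <- c(atlas$roi[atlas$roi_names], atlas$composites)
  vapply(regions, function(idx) sum(supra[idx]) / length(idx), numeric(1))
}

#' Regional involvement flag
#'
#' A composite region counts as involved when at least `min_fraction` of its
#' voxels are suprathreshold inside a surviving cluster. The default 2%
#' makes the flag robust to single stray voxels. The composite "occipital"
#' is calcarine + cuneus + superior/middle/inferior occipital + lingual.
#'
#' @param clusters a `cluster_set`.
#' @param atlas a `dlb_atlas`.
#' @param roi_names region names whose union forms the composite.
#' @param min_fraction involvement threshold in `[0, 1]`.
#' @return logical.
#' @export
roi_involvement <- function(clusters, atlas, roi_names, min_fraction = 0.02) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  idx <- sort(unique(unlist(lapply(roi_names, atlas_region, atlas = atlas))))
  supra <- clusters$labels > 0L
  sum(supra[idx]) / length(idx) >= min_fraction
}

#' Cingulate island sign
#'
#' The ratio between uptake in the posterior cingulate cortex and the sum of
#' the uptake in the precuneus and cuneus regions:
#' `CIS = mean(PCC) / (mean(precuneus) + mean(cuneus))`. Relative
#' preservation of the posterior cingulate amid precuneus/cuneus
#' hypometabolism gives high values, typical of Lewy body dementia. The
#' ratio is invariant to any global rescaling of the input, hence to global
#' mean scaling.
#'
#' @param scan a globally scaled `subject_scan` or 3-D array.
#' @param atlas a `dlb_atlas`.
#' @return the CIS value (> 0 for valid scans).
#' @export
cingulate_island_sign <- function(scan, atlas) {
  vol <- if (inherits(scan, "subject_scan")) scan$volume else scan
  num <- mean(vol[atlas$roi$posterior_cingulate])
  den <- mean(vol[atlas$roi$precuneus]) + mean(vol[atlas$roi$cuneus])
  if (!is.finite(den) || den <= 0) stop("zero or negative CIS denominator")
  num / den
}

#' Optimal CIS cutoff and AUC by ROC analysis
#'
#' Scans all midpoints between adjacent sorted unique values and returns the
#' cutoff maximizing Youden's J = sensitivity + specificity - 1, with the
#' high-CIS group as the positive class (predicted positive when
#' `value >= cutoff`). Ties are broken toward higher sensitivity, then the
#' lower cutoff. The AUC uses the Mann-Whitney identity (ties count 1/2).
#'
#' @param positive CIS values of the positive (high-CIS, DLB-like) group.
#' @param negative CIS values of the comparison group.
#' @return list with `cutoff`, `auc`, `sensitivity` and `specificity` at the
#'   cutoff.
#' @export
cis_cutoff <- function(positive, negative) {
  stopifnot(length(positive) > 0, length(negative) > 0)
  vals <- sort(unique(c(positive, negative)))
  cuts <- if (length(vals) > 1) (vals[-1] + vals[-length(vals)]) / 2 else vals
  sens <- vapply(cuts, function(cc) mean(positive >= cc), numeric(1))
  spec <- vapply(cuts, function(cc) mean(negative < cc), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[sens[best] == max(sens[best])]
  best <- best[which.min(cuts[best])]
  cmp <- outer(positive, negative, function(a, b) (a > b) + 0.5 * (a == b))
  list(cutoff = cuts[best], auc = mean(cmp),
       sensitivity = sens[best], specificity = spec[best])
}

#' Hemispheric asymmetry of suprathreshold hypometabolism
#'
#' With `nL`, `nR` the suprathreshold voxel counts in the left and right
#' hemispheres, `AI = |nL - nR| / max(1, nL + nR)`. A subject is symmetric
#' when `AI <= tau`; an empty map (`nL = nR = 0`) is symmetric with `AI = 0`.
#' The index is a simple, documented stand-in for visual asymmetry
#' assessment; `tau` defaults to 0.5.
#'
#' @param clusters a `cluster_set`.
#' @param atlas a `dlb_atlas`.
#' @param tau symmetry threshold in `[0, 1]`.
#' @return list with `ai`, `symmetric`, `n_left`, `n_right`.
#' @export
asymmetry_index <- function(clusters, atlas, tau = 0.5) {
  supra <- clusters$labels > 0L
  nl <- sum(supra[atlas$left])
  nr <- sum(supra[atlas$right])
  ai <- abs(nl - nr) / max(1, nl + nr)
  list(ai = ai, symmetric = ai <= tau, n_left = nl, n_right = nr)
}

#' Full hallmark profile of one subject
#'
#' Bundles the four discriminative hallmarks computed from the scaled scan
#' and its thresholded cluster map: occipital involvement, cingulate island
#' sign, DLPFC involvement, and the asymmetry index, together with the
#' per-region suprathreshold fractions the pattern rules consume.
#'
#' @param scaled_scan the subject's preprocessed (smoothed, scaled) scan.
#' @param clusters the subject's `cluster_set`.
#' @param atlas a `dlb_atlas`.
#' @param min_fraction involvement threshold for the boolean flags.
#' @param tau symmetry threshold.
#' @return an object of class `hallmark_profile`: `occipital`, `dlpfc`
#'   (logical), `cis`, `ai`, `symmetric`, and `fractions`.
#' @export
hallmark_profile <- function(scaled_scan, clusters, atlas,
                             min_fraction = 0.02, tau = 0.5) {
  fr <- roi_fractions(clusters, atlas)
  asym <- asymmetry_index(clusters, atlas, tau)
  structure(list(
    occipital = unname(fr["occipital"] >= min_fraction),
    dlpfc = unname(fr["dlpfc"] >= min_fraction),
    cis = cingulate_island_sign(scaled_scan, atlas),
    ai = asym$ai, symmetric = asym$symmetric,
    min_fraction = min_fraction, tau = tau,
    fractions = fr
  ), class = "hallmark_profile")
}
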