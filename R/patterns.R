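#' Pattern label levels
#'
#' Fixed label order used for tie-breaking throughout: DLB-like, AD-like,
#' PCA-like (posterior cortical atrophy), PD-like, negative, and the
#' aggregator-only discordant label.
#'
#' @return character vector of the six levels.
#' @export
pattern_levels <- function() {
  c("DLB_LIKE", "AD_LIKE", "PCA_LIKE", "PD_LIKE", "NEGATIVE", "DISCORDANT")
}

#' Rule-based classification of a hypometabolism topography
#'
#' A deterministic decision list standing in for an expert rater reading a
#' thresholded t-map. Involvement of each rule composite (occipital,
#' temporo-parietal, posterior cingulate/precuneus, DLPFC, frontal eye
#' field, premotor/motor) is its suprathreshold fraction reaching the rule's
#' `min_fraction`; asymmetry is `AI > tau`. The decision order:
#' \enumerate{
#'   \item no composite involved: `NEGATIVE`;
#'   \item involvement confined to premotor/motor: `PD_LIKE`;
#'   \item occipital AND temporo-parietal involved: `PCA_LIKE` when the
#'     frontal eye field is involved, the map is asymmetric and the DLPFC is
#'     spared; otherwise `DLB_LIKE`;
#'   \item temporo-parietal and/or posterior cingulate/precuneus involvement
#'     without occipital: `AD_LIKE`;
#'   \item otherwise the label of the most-involved composite (occipital or
#'     DLPFC map to DLB, temporo-parietal or PCC/precuneus to AD, frontal eye
#'     field to PCA, premotor/motor to PD), ties broken in the fixed order
#'     DLB > AD > PCA > PD.
#' }
#'
#' @param hallmarks a `hallmark_profile` (its `fractions` and `ai` are used).
#' @param rule list with `min_fraction` and `tau`; see [default_raters()].
#' @return a single pattern label (never `DISCORDANT`).
#' @export
classify_pattern <- function(hallmarks, rule = list(min_fraction = 0.02, tau = 0.5)) {
  fr <- hallmarks$fractions
  comp <- c("occipital", "temporo_parietal", "pcc_precuneus", "dlpfc",
            "frontal_eye_field", "premotor_motor")
  inv <- fr[comp] >= rule$min_fraction
  asym <- hallmarks$ai > rule$tau
  if (!any(inv)) return("NEGATIVE")
  if (inv[["premotor_motor"]] && !any(inv[comp != "premotor_motor"]))
    return("PD_LIKE")
  if (inv[["occipital"]] && inv[["temporo_parietal"]]) {
    if (inv[["frontal_eye_field"]] && asym && !inv[["dlpfc"]]) return("PCA_LIKE")
    return("DLB_LIKE")
  }
  if ((inv[["temporo_parietal"]] || inv[["pcc_precuneus"]]) && !inv[["occipital"]])
    return("AD_LIKE")
  label_of <- c(occipital = "DLB_LIKE", temporo_parietal = "AD_LIKE",
                pcc_precuneus = "AD_LIKE", dlpfc = "DLB_LIKE",
                frontal_eye_field = "PCA_LIKE", premotor_motor = "PD_LIKE")
  cand <- comp[inv]
  cand <- cand[order(-fr[cand], match(label_of[cand], pattern_levels()))]
  unname(label_of[cand[1L]])
}

#' Four synthetic rater rule variants
#'
#' Four parameterizations of the decision list stand in for four independent
#' human experts: involvement thresholds 1%, 2%, 2%, 5% and symmetry
#' thresholds 0.4, 0.5, 0.5, 0.6. The spread synthesizes the between-rater
#' variance a supermajority vote is meant to absorb.
#'
#' @return list of four rules (`min_fraction`, `tau`, `id`).
#' @export
default_raters <- function() {
  mf <- c(0.01, 0.02, 0.02, 0.05)
  tau <- c(0.4, 0.5, 0.5, 0.6)
  lapply(1:4, function(i) list(min_fraction = mf[i], tau = tau[i],
                               id = sprintf("rater%d", i)))
}

#' Supermajority vote over rater labels
#'
#' Returns the label reached by at least `quorum` raters (more than a simple
#' majority); otherwise `DISCORDANT`, with the plurality label attached as
#' attribute `"plurality"` for adjudication (plurality ties broken by the
#' fixed label order).
#'
#' @param labels character vector of rater labels (>= 3).
#' @param quorum required agreement count (> half the raters).
#' @return a pattern label, possibly `DISCORDANT`.
#' @export
supermajority_vote <- function(labels, quorum = 3L) {
  if (!length(labels)) stop("empty label list")
  stopifnot(length(labels) >= 3, quorum > length(labels) / 2)
  lev <- pattern_levels()
  counts <- table(factor(labels, levels = lev))
  top <- which.max(counts)  # first max in fixed level order
  if (counts[top] >= quorum) return(names(counts)[top])
  structure("DISCORDANT", plurality = names(counts)[top])
}

#' Mean pairwise Cohen's kappa across raters
#'
#' Cohen's kappa on the multi-class labels for every rater pair, averaged.
#' Pairs whose chance-agreement denominator vanishes (a degenerate constant
#' rater agreeing perfectly with chance) are excluded with a warning.
#'
#' @param label_matrix subjects x raters matrix (or data.frame) of labels.
#' @return mean pairwise kappa.
#' @export
mean_pairwise_kappa <- function(label_matrix) {
  m <- as.matrix(label_matrix)
  stopifnot(ncol(m) >= 2, nrow(m) >= 2)
  pairs <- utils::combn(ncol(m), 2)
  ks <- apply(pairs, 2, function(p) cohen_kappa(m[, p[1L]], m[, p[2L]]))
  if (anyNA(ks)) warning("kappa undefined for some rater pair(s); excluded")
  mean(ks, na.rm = TRUE)
}

#' Cohen's kappa for two label vectors
#'
#' @param x,y label vectors of equal length.
#' @return kappa, or `NA` when the chance-corrected denominator is zero.
#' @export
cohen_kappa <- function(x, y) {
  stopifnot(length(x) == length(y))
  lev <- sort(unique(c(x, y)))
  fx <- factor(x, levels = lev); fy <- factor(y, levels = lev)
  po <- mean(fx == fy)
  pe <- sum(prop.table(table(fx)) * prop.table(table(fy)))
  if (1 - pe == 0) return(NA_real_)
  (po - pe) / (1 - pe)
}
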