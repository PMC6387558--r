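#' Subjects x ROI hypometabolism feature matrix
#'
#' Entry (s, r) is the mean unthresholded t value over the in-mask voxels of
#' ROI r for subject s (hypometabolism-positive). The 14 analysis ROIs are
#' used in their fixed atlas order.
#'
#' @param tmaps list of `tmap`s sharing grid and mask.
#' @param atlas a `dlb_atlas`.
#' @return numeric matrix, one row per subject, with ROI column names and
#'   subject row names when the t-maps are named.
#' @export
build_feature_matrix <- function(tmaps, atlas) {
  stopifnot(length(tmaps) >= 1, inherits(atlas, "dlb_atlas"))
  mask <- tmaps[[1L]]$mask
  roi_idx <- lapply(atlas$roi[atlas$roi_names], function(idx) {
    keep <- idx[mask[idx]]
    if (!length(keep)) stop("ROI entirely outside the analysis mask")
    keep
  })
  out <- t(vapply(tmaps, function(tm) {
    if (!identical(dim(tm$t), dim(mask))) stop("t-maps must share one grid")
    vapply(roi_idx, function(idx) mean(tm$t[idx]), numeric(1))
  }, numeric(length(roi_idx))))
  colnames(out) <- atlas$roi_names
  rownames(out) <- names(tmaps)
  out
}

#' PCA dimensionality reduction
#'
#' Columns are centred (and by default standardized); the smallest number of
#' principal components whose cumulative explained variance reaches
#' `variance_target` is retained and the corresponding scores returned.
#'
#' @param x feature matrix (>= 3 rows).
#' @param variance_target cumulative explained-variance target in (0, 1].
#' @param scale standardize columns (constant columns are left centred only).
#' @return list with `scores`, `ncomp`, `explained` (per-component
#'   proportions) and the `prcomp` fit.
#' @export
pca_reduce <- function(x, variance_target = 0.80, scale = TRUE) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 3)
  if (variance_target <= 0 || variance_target > 1)
    stop("variance_target must lie in (0, 1]")
  x <- scale(x, center = TRUE, scale = FALSE)
  if (scale) {
    sds <- apply(x, 2, stats::sd)
    sds[sds == 0] <- 1          # constant columns stay centred only
    x <- sweep(x, 2, sds, "/")
  }
  fit <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  ev <- fit$sdev^2
  explained <- ev / sum(ev)
  ncomp <- which(cumsum(explained) >= variance_target - 1e-12)[1L]
  list(scores = fit$x[, seq_len(ncomp), drop = FALSE], ncomp = ncomp,
       explained = explained, fit = fit)
}

#' Hierarchical clustering: supremum-norm distances, Ward linkage
#'
#' Pairwise Chebyshev (L-infinity) distances with Ward agglomeration via the
#' Lance-Williams update applied to the squared dissimilarities (Ward on a
#' non-Euclidean metric is formally improper but is applied as specified;
#' heights are reported on the original distance scale, i.e. as square roots
#' of the updated squared dissimilarities, the `ward.D2` convention). Ties
#' are broken deterministically toward the pair of lowest cluster slots.
#'
#' @param scores numeric matrix (>= 2 rows), e.g. PCA scores.
#' @return an `hclust` object (merge, height, order, labels), usable with
#'   [stats::cutree()] and [cut_tree()].
#' @export
hcluster_chebyshev_ward <- function(scores) {
  x <- as.matrix(scores)
  n <- nrow(x)
  stopifnot(n >= 2)
  d2 <- as.matrix(stats::dist(x, method = "maximum"))^2
  active <- rep(TRUE, n)
  size <- rep(1, n)
  id <- -(seq_len(n))        # hclust coding: negative singleton, positive merge
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  diag(d2) <- Inf
  d2[lower.tri(d2)] <- Inf   # scan upper triangle only
  for (s in seq_len(n - 1L)) {
    m <- min(d2[active, active, drop = FALSE][])
    cand <- which(d2 == m & outer(active, active, `&`), arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    height[s] <- sqrt(m)
    pair <- sort(c(id[i], id[j]))
    merge[s, ] <- pair
    others <- which(active); others <- others[others != i & others != j]
    for (k in others) {
      dki <- if (k < i) d2[k, i] else d2[i, k]
      dkj <- if (k < j) d2[k, j] else d2[j, k]
      upd <- ((size[i] + size[k]) * dki + (size[j] + size[k]) * dkj -
                size[k] * m) / (size[i] + size[j] + size[k])
      if (k < i) d2[k, i] <- upd else d2[i, k] <- upd
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    id[i] <- s
  }
  structure(list(merge = merge, height = height,
                 order = .dendro_order(merge, n),
                 labels = rownames(x), method = "ward.D2",
                 dist.method = "chebyshev"),
            class = "hclust")
}

.dendro_order <- function(merge, n) {
  leaves <- function(row) {
    out <- integer(0)
    stack <- c(row)
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      if (v < 0) out <- c(out, -v)
      else stack <- c(merge[v, 1L], merge[v, 2L], stack)
    }
    out
  }
  if (n == 1L) return(1L)
  leaves(n - 1L)
}

#' Cut a dendrogram into k subgroups
#'
#' Removes the `k - 1` highest merges; subgroup 1 is the largest (ties by
#' the original cutree label).
#'
#' @param dendrogram an `hclust`, e.g. from [hcluster_chebyshev_ward()].
#' @param k number of subgroups, `1 <= k <= n`.
#' @return integer labels, 1 = largest subgroup.
#' @export
cut_tree <- function(dendrogram, k) {
  n <- length(dendrogram$height) + 1L
  if (k < 1 || k > n) stop("invalid k")
  cl <- stats::cutree(dendrogram, k = k)
  sizes <- table(cl)
  ord <- order(-sizes, as.integer(names(sizes)))
  remap <- integer(length(sizes))
  remap[as.integer(names(sizes))[ord]] <- seq_along(ord)
  unname(remap[cl])
}

#' Mean silhouette widths for a range of cuts
#'
#' Simple silhouette on the Chebyshev distances, as guidance for choosing
#' the number of subgroups (the cut itself is a user decision).
#'
#' @param scores score matrix.
#' @param dendrogram matching `hclust`.
#' @param ks candidate numbers of clusters.
#' @return named numeric vector of mean silhouette widths.
#' @export
silhouette_guidance <- function(scores, dendrogram, ks = 2:6) {
  d <- as.matrix(stats::dist(scores, method = "maximum"))
  out <- vapply(ks, function(k) {
    cl <- cut_tree(dendrogram, k)
    if (length(unique(cl)) < 2) return(NA_real_)
    sil <- vapply(seq_len(nrow(d)), function(i) {
      own <- cl == cl[i]; own[i] <- FALSE
      a <- if (any(own)) mean(d[i, own]) else 0
      b <- min(vapply(setdiff(unique(cl), cl[i]),
                      function(g) mean(d[i, cl == g]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1))
    mean(sil)
  }, numeric(1))
  names(out) <- ks
  out
}

#' Compare clinical features between two subgroups
#'
#' Binary features (logical or 0/1) are tested with the uncorrected Pearson
#' chi-square on their 2x2 counts; continuous features with Welch's t-test.
#'
#' @param labels subgroup labels (two groups).
#' @param clinical_table data.frame of per-subject clinical features, rows
#'   aligned with `labels`.
#' @return data.frame: feature, type, statistic, p.
#' @export
subgroup_compare <- function(labels, clinical_table) {
  stopifnot(nrow(clinical_table) == length(labels))
  gs <- sort(unique(labels))
  if (length(gs) != 2) stop("exactly two subgroups required")
  rows <- lapply(names(clinical_table), function(nm) {
    v <- clinical_table[[nm]]
    if (is.logical(v) || all(v %in% c(0, 1, NA))) {
      tab <- rbind(c(sum(v[labels == gs[1]] == 1, na.rm = TRUE),
                     sum(v[labels == gs[1]] == 0, na.rm = TRUE)),
                   c(sum(v[labels == gs[2]] == 1, na.rm = TRUE),
                     sum(v[labels == gs[2]] == 0, na.rm = TRUE)))
      ## a feature identical across subjects has a zero margin: statistic 0
      if (any(colSums(tab) == 0))
        return(data.frame(feature = nm, type = "binary", statistic = 0, p = 1))
      ct <- pearson_chi2(tab)
      data.frame(feature = nm, type = "binary", statistic = ct$statistic, p = ct$p)
    } else {
      x <- v[labels == gs[1]]; y <- v[labels == gs[2]]
      if (length(x) < 2 || length(y) < 2) stop("subgroup too small for a t-test")
      if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y))
        return(data.frame(feature = nm, type = "continuous", statistic = 0, p = 1))
      wt <- welch_t(x, y)
      data.frame(feature = nm, type = "continuous", statistic = wt$t, p = wt$p)
    }
  })
  do.call(rbind, rows)
}
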