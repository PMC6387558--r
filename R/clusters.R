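#' Suprathreshold clusters of a thresholded t-map
#'
#' Connected components of `{t >= threshold}` under 6-, 18- or 26-neighbour
#' connectivity; components smaller than the extent threshold `k` are
#' discarded and the survivors relabelled `1..C` by decreasing size. The
#' default connectivity (18) matches common neuroimaging practice.
#'
#' @param tmap a `tmap`; if its `threshold` slot is set it is used unless
#'   `t_threshold` is given.
#' @param t_threshold voxel-level t threshold.
#' @param k minimum cluster extent in voxels (>= 1); clusters with
#'   `size >= k` survive (use `strict_gt = TRUE` for `size > k`).
#' @param connectivity one of 6, 18, 26.
#' @param strict_gt require strictly more than `k` voxels.
#' @return an object of class `cluster_set`: integer label volume (`0` =
#'   background), per-cluster `sizes`, `peak_t`, `peak_ijk` (one row per
#'   cluster), and the thresholds used. An empty set is valid.
#' @export
extract_clusters <- function(tmap, t_threshold = NULL, k = 13L,
                             connectivity = 18L, strict_gt = FALSE) {
  stopifnot(inherits(tmap, "tmap"), k >= 1)
  if (is.null(t_threshold)) t_threshold <- tmap$threshold
  if (!is.finite(t_threshold)) stop("no t threshold available")
  supra <- !is.na(tmap$t) & tmap$t >= t_threshold
  lab <- label_components(supra, connectivity)
  ncomp <- max(lab)
  keep <- integer(0)
  if (ncomp > 0) {
    sizes <- tabulate(lab[lab > 0L], ncomp)
    keep <- which(if (strict_gt) sizes > k else sizes >= k)
  }
  out_lab <- array(0L, dim(lab))
  out_sizes <- integer(0); peak_t <- numeric(0); peak_ijk <- NULL
  if (length(keep)) {
    sizes <- tabulate(lab[lab > 0L], ncomp)
    keep <- keep[order(-sizes[keep], keep)]
    peak_ijk <- matrix(0L, length(keep), 3L)
    for (new in seq_along(keep)) {
      idx <- which(lab == keep[new])
      out_lab[idx] <- new
      out_sizes[new] <- length(idx)
      tv <- tmap$t[idx]
      pk <- idx[which.max(tv)]
      peak_t[new] <- max(tv)
      peak_ijk[new, ] <- arrayInd(pk, dim(lab))
    }
  }
  structure(list(labels = out_lab, sizes = out_sizes, peak_t = peak_t,
                 peak_ijk = peak_ijk, k = k, connectivity = connectivity,
                 threshold = t_threshold, strict_gt = strict_gt),
            class = "cluster_set")
}

#' Label connected components of a binary 3-D volume
#'
#' Minimum-label propagation restricted to the bounding box of the foreground:
#' every foreground voxel starts with a unique label and iteratively adopts
#' the smallest label among its neighbours until a fixed point, which yields
#' maximal connected components. Deterministic.
#'
#' @param mask logical 3-D array.
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (all neighbours).
#' @return integer array of component labels (`0` = background), numbered
#'   `1..C` in first-voxel order.
#' @export
label_components <- function(mask, connectivity = 18L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  offsets <- .connectivity_offsets(connectivity)
  out <- array(0L, dim(mask))
  fg <- which(mask)
  if (!length(fg)) return(out)

  ## crop to the foreground bounding box (with a 1-voxel margin) for speed
  ijk <- arrayInd(fg, dim(mask))
  lo <- pmax(1L, apply(ijk, 2L, min) - 1L)
  hi <- pmin(dim(mask), apply(ijk, 2L, max) + 1L)
  sub <- mask[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
  dim(sub) <- hi - lo + 1L

  lab <- array(Inf, dim(sub))
  sfg <- which(sub)
  lab[sfg] <- sfg
  repeat {
    new <- lab
    for (o in offsets) {
      new <- pmin(new, .shift_num(lab, o, Inf))
    }
    new[!sub] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  comp <- match(lab[sfg], sort(unique(lab[sfg])))
  subout <- array(0L, dim(sub))
  subout[sfg] <- comp
  out[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]] <- subout
  out
}

.connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be one of 6, 18, 26")
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  manh <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  g <- switch(as.character(connectivity),
              "6" = g[manh == 1, ], "18" = g[manh <= 2, ], "26" = g)
  lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
}

## shift a numeric 3-D array by an integer offset, padding with `fill`
.shift_num <- function(a, off, fill) {
  n <- dim(a)
  out <- array(fill, n)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    d <- off[ax]
    if (d >= 0) { dst[[ax]] <- seq_len(n[ax] - d) + d; src[[ax]] <- seq_len(n[ax] - d) }
    else { dst[[ax]] <- seq_len(n[ax] + d); src[[ax]] <- seq_len(n[ax] + d) - d }
    if (!length(dst[[ax]])) return(out)
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

#' Cluster extent in voxels for a physical extent in mm^3
#'
#' Extent thresholds quoted in voxels are grid-dependent; this converts a
#' physical cluster volume to a voxel count for the current grid (ceiling).
#' The default, 800 mm^3, corresponds to 100 voxels of 2 mm edge.
#'
#' @param voxel_mm voxel size in mm (scalar or length 3).
#' @param extent_mm3 physical extent in mm^3.
#' @return integer voxel count (>= 1).
#' @export
extent_voxels <- function(voxel_mm, extent_mm3 = 800) {
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  max(1L, as.integer(ceiling(extent_mm3 / prod(voxel_mm))))
}
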