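#' Build the schematic brain atlas used throughout the pipeline
#'
#' The atlas is a deterministic, geometric stand-in for the anatomical
#' parcellations used in clinical FDG-PET work: 14 analysis regions of
#' interest (occipital, temporal, parietal and frontal parcels known to be
#' involved in Lewy body dementia) plus auxiliary masks (premotor/motor strip,
#' frontal eye fields, superior parietal cortex, hemispheres, whole brain).
#' Parcels are axis-aligned boxes placed in anatomically plausible relative
#' positions: occipital parcels posterior, DLPFC anterior-superior, posterior
#' cingulate and precuneus medial-posterior. Only the topological relations
#' the classification rules rely on (posterior vs anterior, medial vs
#' lateral, left vs right) are guaranteed, not anatomical shape.
#'
#' All bilateral parcels are mirror-symmetric about the midsagittal plane, so
#' hemispheric asymmetry of a symmetric process is exactly zero by
#' construction. The first grid axis is left-right, the second
#' posterior-anterior, the third inferior-superior.
#'
#' @param grid_shape integer vector of length 3, voxels per axis (each >= 24).
#' @param voxel_size_mm voxel edge length in mm (scalar or length 3).
#' @return An object of class `dlb_atlas`: a list with elements `dim`,
#'   `voxel_mm`, `roi` (named list of linear voxel indices for the 14
#'   analysis ROIs), `roi_names` (their fixed order), `aux` (premotor/motor,
#'   frontal eye field, parietal), `composites` (index unions used by the
#'   pattern rules), `left`, `right`, and `brain` (logical array).
#' @export
make_atlas <- function(grid_shape = c(40L, 48L, 40L), voxel_size_mm = 4) {
  if (length(grid_shape) != 3L || any(!is.finite(grid_shape)))
    stop("grid_shape must be three voxel counts")
  grid_shape <- as.integer(grid_shape)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (any(grid_shape < 24L))
    stop("grid too small: cannot place ROIs (need >= 24 voxels per axis)")

  n <- grid_shape
  boxes <- .atlas_boxes()

  idx_of <- function(b) .box_indices(b, n)
  roi_names <- c(
    "calcarine", "cuneus", "occipital_sup", "occipital_mid", "occipital_inf",
    "fusiform", "lingual", "temporal_inf", "temporal_mid", "temporal_sup",
    "precuneus", "dlpfc", "posterior_cingulate", "angular"
  )
  aux_names <- c("premotor_motor", "frontal_eye_field", "parietal")

  roi <- lapply(boxes[roi_names], idx_of)
  aux <- lapply(boxes[aux_names], idx_of)

  all_regions <- c(roi, aux)
  for (nm in names(all_regions)) {
    if (length(all_regions[[nm]]) < 20L)
      stop(sprintf("cannot place ROIs: region '%s' has %d voxels (< 20)",
                   nm, length(all_regions[[nm]])))
  }
  ## disjointness is part of the atlas contract; verify rather than trust
  all_idx <- unlist(all_regions, use.names = FALSE)
  if (anyDuplicated(all_idx)) {
    dup <- all_idx[duplicated(all_idx)][1L]
    hit <- names(all_regions)[vapply(all_regions, function(i) dup %in% i, logical(1))]
    stop(sprintf("atlas regions overlap: %s", paste(hit, collapse = ", ")))
  }

  brain <- .atlas_brain(n, all_regions)

  half <- n[1L] %/% 2L
  xcoord <- slice.index(array(0, n), 1L)
  left <- brain & (xcoord <= half)
  right <- brain & (xcoord >= n[1L] + 1L - half)

  composites <- list(
    occipital = sort(unlist(roi[c("calcarine", "cuneus", "occipital_sup",
                                  "occipital_mid", "occipital_inf", "lingual")],
                            use.names = FALSE)),
    temporo_parietal = sort(c(unlist(roi[c("temporal_inf", "temporal_mid",
                                           "temporal_sup", "angular")],
                                     use.names = FALSE), aux$parietal)),
    pcc_precuneus = sort(unlist(roi[c("posterior_cingulate", "precuneus")],
                                use.names = FALSE)),
    dlpfc = roi$dlpfc,
    frontal_eye_field = aux$frontal_eye_field,
    premotor_motor = aux$premotor_motor
  )

  structure(list(
    dim = n, voxel_mm = as.numeric(voxel_size_mm),
    roi = roi, roi_names = roi_names, aux = aux,
    composites = composites,
    left = left, right = right, brain = brain
  ), class = "dlb_atlas")
}

#' Look up a named region of an atlas
#'
#' Resolves, in order, one of the 14 analysis ROIs, an auxiliary mask, or a
#' composite used by the pattern rules.
#'
#' @param atlas a `dlb_atlas`.
#' @param name region name.
#' @return integer vector of linear voxel indices.
#' @export
atlas_region <- function(atlas, name) {
  stopifnot(inherits(atlas, "dlb_atlas"))
  if (name %in% names(atlas$roi)) return(atlas$roi[[name]])
  if (name %in% names(atlas$aux)) return(atlas$aux[[name]])
  if (name %in% names(atlas$composites)) return(atlas$composites[[name]])
  stop(sprintf("unknown ROI name '%s'", name))
}

## Parcel geometry in fractional grid coordinates [0, 1).  `lateral` parcels
## are given for the left hemisphere and mirrored to the right; medial parcels
## span the midline symmetrically.  Fractions, not voxel indices, so any grid
## >= 24 voxels per axis hosts the same topology.
.atlas_boxes <- function() {
  b <- function(x, y, z, lateral = FALSE) list(x = x, y = y, z = z, lateral = lateral)
  list(
    calcarine           = b(c(0.40, 0.60), c(0.0417, 0.125), c(0.375, 0.525)),
    cuneus              = b(c(0.40, 0.60), c(0.0417, 0.125), c(0.525, 0.675)),
    lingual             = b(c(0.40, 0.60), c(0.0417, 0.125), c(0.225, 0.375)),
    precuneus           = b(c(0.40, 0.60), c(0.1667, 0.2708), c(0.525, 0.675)),
    posterior_cingulate = b(c(0.40, 0.60), c(0.1667, 0.2708), c(0.375, 0.500)),
    occipital_sup       = b(c(0.10, 0.25), c(0.0625, 0.1667), c(0.575, 0.700), TRUE),
    occipital_mid       = b(c(0.10, 0.25), c(0.0625, 0.1667), c(0.400, 0.550), TRUE),
    occipital_inf       = b(c(0.10, 0.25), c(0.0625, 0.1667), c(0.250, 0.375), TRUE),
    fusiform            = b(c(0.10, 0.25), c(0.1875, 0.3125), c(0.125, 0.225), TRUE),
    temporal_inf        = b(c(0.10, 0.25), c(0.3125, 0.4583), c(0.175, 0.275), TRUE),
    temporal_mid        = b(c(0.10, 0.25), c(0.3125, 0.4583), c(0.300, 0.400), TRUE),
    temporal_sup        = b(c(0.10, 0.25), c(0.3125, 0.4583), c(0.425, 0.525), TRUE),
    angular             = b(c(0.10, 0.25), c(0.2292, 0.3333), c(0.575, 0.700), TRUE),
    dlpfc               = b(c(0.075, 0.25), c(0.6458, 0.7917), c(0.575, 0.750), TRUE),
    frontal_eye_field   = b(c(0.30, 0.40), c(0.6458, 0.7292), c(0.625, 0.725), TRUE),
    parietal            = b(c(0.25, 0.425), c(0.2708, 0.4375), c(0.6125, 0.750), TRUE),
    premotor_motor      = b(c(0.15, 0.85), c(0.5208, 0.6042), c(0.6875, 0.825))
  )
}

## voxel v (1-based) is inside a fractional interval [lo, hi) iff its centre
## (v - 0.5)/n falls inside; this makes mirrored boxes exact voxel mirrors
.frac_range <- function(lo, hi, n) {
  v1 <- ceiling(lo * n + 0.5)
  v2 <- ceiling(hi * n + 0.5) - 1L
  if (v2 < v1) integer(0) else seq.int(v1, v2)
}

.box_indices <- function(box, n) {
  xs <- .frac_range(box$x[1L], box$x[2L], n[1L])
  ys <- .frac_range(box$y[1L], box$y[2L], n[2L])
  zs <- .frac_range(box$z[1L], box$z[2L], n[3L])
  if (isTRUE(box$lateral)) xs <- sort(unique(c(xs, n[1L] + 1L - xs)))
  if (!length(xs) || !length(ys) || !length(zs)) return(integer(0))
  grid <- expand.grid(x = xs, y = ys, z = zs)
  sort(grid$x + n[1L] * (grid$y - 1L) + n[1L] * n[2L] * (grid$z - 1L))
}

## brain support: a midline-symmetric ellipsoid plus every parcel dilated by
## two voxels, so all parcels sit strictly inside brain tissue
.atlas_brain <- function(n, regions) {
  cx <- (n + 1) / 2
  rad <- c(0.47, 0.48, 0.47) * n
  x <- slice.index(array(0, n), 1L)
  y <- slice.index(array(0, n), 2L)
  z <- slice.index(array(0, n), 3L)
  brain <- ((x - cx[1L]) / rad[1L])^2 + ((y - cx[2L]) / rad[2L])^2 +
    ((z - cx[3L]) / rad[3L])^2 <= 1
  pad <- array(FALSE, n)
  pad[unlist(regions, use.names = FALSE)] <- TRUE
  for (ax in 1:3) pad <- .dilate_axis(pad, ax, 2L)
  brain | pad
}

.dilate_axis <- function(mask, axis, r) {
  out <- mask
  nd <- dim(mask)[axis]
  for (d in seq_len(r)) {
    out <- out | .shift_logical(mask, axis, d) | .shift_logical(mask, axis, -d)
  }
  out
}

.shift_logical <- function(a, axis, d) {
  out <- array(FALSE, dim(a))
  n <- dim(a)
  src <- vector("list", 3L); dst <- vector("list", 3L)
  for (ax in 1:3) { src[[ax]] <- seq_len(n[ax]); dst[[ax]] <- seq_len(n[ax]) }
  if (d > 0) { dst[[axis]] <- (1 + d):n[axis]; src[[axis]] <- 1:(n[axis] - d) }
  if (d < 0) { dst[[axis]] <- 1:(n[axis] + d); src[[axis]] <- (1 - d):n[axis] }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}
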