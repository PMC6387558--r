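#' Read a 3-D NIfTI uptake volume
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param age,id,cohort optional metadata attached to the scan.
#' @return a `subject_scan`.
#' @export
read_scan <- function(path, age = NA_real_, id = basename(path),
                      cohort = NA_character_) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3-D volume, got %d dimensions", length(d)))
  vol <- as.array(img)
  if (any(!is.finite(vol))) stop("volume contains non-finite voxels")
  voxel <- RNifti::pixdim(img)[1:3]
  structure(list(volume = vol, age = age, id = id, cohort = cohort,
                 pattern = NA_character_, voxel_mm = voxel, dim = d),
            class = "subject_scan")
}

#' Write a volume as NIfTI-1
#'
#' Volumes are stored as float32 with a diagonal affine built from the voxel
#' size; all statistics in the package are computed in float64.
#'
#' @param x a `subject_scan` or 3-D array.
#' @param path destination (`.nii` or `.nii.gz`).
#' @param voxel_mm voxel size, required for bare arrays.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, voxel_mm = NULL) {
  vol <- if (inherits(x, "subject_scan")) x$volume else x
  if (is.null(voxel_mm)) {
    voxel_mm <- if (inherits(x, "subject_scan")) x$voxel_mm else stop("voxel_mm required")
  }
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  img <- RNifti::asNifti(structure(vol, pixdim = voxel_mm), datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a tab-delimited table
#'
#' UTF-8, tab-delimited, header row, no quoting: the exchange format for all
#' per-subject tables in the pipeline.
#'
#' @param df data.frame.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-delimited table
#'
#' @param path file written by [write_tsv()].
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

#' Default pipeline configuration
#'
#' All module settings in one serializable list: phantom cohort sizes and
#' effect parameters, preprocessing (smoothing FWHM in mm, analysis-mask
#' fraction, scaling target), t-map settings (FWE alpha, physical cluster
#' extent in mm^3, connectivity, age covariate), hallmark thresholds, the
#' rater rule variants with the vote quorum, and subtype settings.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    phantom = list(n_controls = 112L,
                   n_patients = c(DLB = 25L, ADD = 25L, PCA = 25L, PD = 25L),
                   control_age_mean = 64.68, control_age_sd = 9.35,
                   patient_age_mean = 71, patient_age_sd = 8,
                   global_sdlog = 0.15, noise_sd = 0.05,
                   asymmetry_factor = 6, age_slope = 0),
    grid = list(shape = c(40L, 48L, 40L), voxel_mm = 4),
    preproc = list(fwhm_mm = 8, mask_fraction = 0.8, target = 1),
    tmap = list(alpha = 0.05, extent_mm3 = 800, connectivity = 18L,
                use_age = TRUE),
    hallmarks = list(min_fraction = 0.02, tau = 0.5),
    vote_quorum = 3L,
    subtype = list(k = 2L, variance_target = 0.80, scale = TRUE),
    seed = 1L
  )
}

#' Read and validate a pipeline configuration from JSON
#'
#' Unknown keys (at the top level or inside a known section) are rejected to
#' catch typos; missing keys fall back to [default_config()].
#'
#' @param path JSON file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_config(cfg)
}

#' Validate and complete a configuration list
#'
#' @param cfg partial configuration.
#' @return completed configuration with defaults filled in.
#' @export
validate_config <- function(cfg) {
  def <- default_config()
  bad <- setdiff(names(cfg), names(def))
  if (length(bad)) stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  for (sec in names(cfg)) {
    if (is.list(def[[sec]]) && is.list(cfg[[sec]])) {
      badk <- setdiff(names(cfg[[sec]]), names(def[[sec]]))
      if (length(badk))
        stop(sprintf("unknown config key(s) in '%s': %s", sec, paste(badk, collapse = ", ")))
      def[[sec]] <- utils::modifyList(def[[sec]], cfg[[sec]])
    } else {
      def[[sec]] <- cfg[[sec]]
    }
  }
  def
}

## stable rolling hash of the serialized configuration, for output manifests
config_hash <- function(cfg) {
  s <- as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
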