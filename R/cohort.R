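#' Default disease-pattern templates for the phantom generator
#'
#' Each template names the atlas regions whose uptake is fractionally reduced
#' and emulates the topography of a disease-specific hypometabolism pattern:
#' \describe{
#'   \item{DLB}{medial and lateral occipital plus temporo-parietal and
#'     frontal (DLPFC) reductions; precuneus reduced, posterior cingulate
#'     spared (the substrate of the cingulate island sign).}
#'   \item{ADD}{bilateral temporo-parietal plus posterior
#'     cingulate/precuneus reductions, occipital spared.}
#'   \item{PCA}{asymmetric posterior (occipital + temporo-parietal)
#'     reductions with frontal-eye-field foci and spared DLPFC.}
#'   \item{PD}{a mild reduction confined to the premotor/motor strip.}
#' }
#' Fractional effect sizes (0.15-0.25) are calibration choices of this
#' package, not measured clinical values.
#'
#' @return named list of pattern templates; each has `rois` (named vector of
#'   fractional reductions in `[0,1)`) and `asymmetric` (logical).
#' @export
default_patterns <- function() {
  occ <- c(calcarine = 0.25, cuneus = 0.25, occipital_sup = 0.25,
           occipital_mid = 0.25, occipital_inf = 0.25, lingual = 0.25)
  tp20 <- c(temporal_inf = 0.20, temporal_mid = 0.20, temporal_sup = 0.20,
            angular = 0.20, parietal = 0.20)
  tp25 <- c(temporal_inf = 0.25, temporal_mid = 0.25, temporal_sup = 0.25,
            angular = 0.25, parietal = 0.25)
  list(
    DLB = list(rois = c(occ, fusiform = 0.20, tp20, precuneus = 0.25,
                        dlpfc = 0.15), asymmetric = FALSE),
    ADD = list(rois = c(tp25, posterior_cingulate = 0.25, precuneus = 0.25),
               asymmetric = FALSE),
    PCA = list(rois = c(occ, tp20, frontal_eye_field = 0.25),
               asymmetric = TRUE),
    PD = list(rois = c(premotor_motor = 0.20), asymmetric = FALSE)
  )
}

#' Specify a synthetic cohort
#'
#' Collects every knob of the phantom generator: cohort sizes, age
#' distributions, disease-pattern templates, between-subject global-uptake
#' variability (lognormal), additive voxel noise (as a fraction of tissue
#' uptake), the hemispheric asymmetry factor applied to asymmetric patterns,
#' an optional linear age effect on regional uptake, and the master seed.
#'
#' Defaults emulate the normative database the analysis assumes (112
#' controls, age 64.68 +/- 9.35 years) and mid-range disease effect sizes.
#'
#' @param n_controls number of control subjects.
#' @param n_patients named integer vector, patients per pattern.
#' @param control_age_mean,control_age_sd control age distribution (years).
#' @param patient_age_mean,patient_age_sd patient age distribution (years).
#' @param patterns pattern templates, see [default_patterns()].
#' @param global_sdlog sdlog of the lognormal subject-level global uptake factor.
#' @param noise_sd additive Gaussian voxel noise, as a fraction of baseline
#'   tissue uptake.
#' @param asymmetry_factor for asymmetric patterns, the left-hemisphere
#'   reduction is `r` and the right-hemisphere reduction `r / asymmetry_factor`.
#' @param age_slope per-year multiplicative change of ROI uptake relative to
#'   the reference age (`control_age_mean`); default 0.
#' @param seed master seed; a fixed seed makes every volume and table
#'   bit-reproducible.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 112L,
                        n_patients = c(DLB = 25L, ADD = 25L, PCA = 25L, PD = 25L),
                        control_age_mean = 64.68, control_age_sd = 9.35,
                        patient_age_mean = 71, patient_age_sd = 8,
                        patterns = default_patterns(),
                        global_sdlog = 0.15, noise_sd = 0.05,
                        asymmetry_factor = 6, age_slope = 0, seed = 1L) {
  stopifnot(n_controls >= 0, all(n_patients >= 0),
            control_age_sd >= 0, patient_age_sd >= 0,
            global_sdlog >= 0, noise_sd >= 0, asymmetry_factor >= 1)
  for (nm in names(patterns)) {
    red <- patterns[[nm]]$rois
    if (any(red < 0) || any(red >= 1))
      stop(sprintf("pattern '%s': fractional reductions must lie in [0, 1)", nm))
  }
  if (length(n_patients) && is.null(names(n_patients)))
    stop("n_patients must be a named vector of pattern counts")
  structure(list(
    n_controls = as.integer(n_controls), n_patients = n_patients,
    control_age_mean = control_age_mean, control_age_sd = control_age_sd,
    patient_age_mean = patient_age_mean, patient_age_sd = patient_age_sd,
    patterns = patterns, global_sdlog = global_sdlog, noise_sd = noise_sd,
    asymmetry_factor = asymmetry_factor, age_slope = age_slope,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

## evaluate expr under a local RNG state, leaving the caller's RNG untouched
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## noise-free uptake template: 1.0 inside the brain, ROI uptake modulated by
## the (optional) linear age effect
.control_template <- function(atlas, age, spec) {
  vol <- array(0, atlas$dim)
  vol[atlas$brain] <- 1
  if (spec$age_slope != 0) {
    f <- max(0.05, 1 + spec$age_slope * (age - spec$control_age_mean))
    for (nm in atlas$roi_names) vol[atlas$roi[[nm]]] <- vol[atlas$roi[[nm]]] * f
  }
  vol
}

.new_scan <- function(volume, age, id, cohort, pattern, atlas) {
  structure(list(volume = volume, age = age, id = id, cohort = cohort,
                 pattern = pattern, voxel_mm = atlas$voxel_mm,
                 dim = atlas$dim), class = "subject_scan")
}

.add_subject_noise <- function(template, atlas, spec, seed, global_factor) {
  .with_seed(seed, {
    g <- if (is.null(global_factor)) stats::rlnorm(1, 0, spec$global_sdlog) else global_factor
    vol <- template
    if (spec$noise_sd > 0) {
      nb <- sum(atlas$brain)
      vol[atlas$brain] <- vol[atlas$brain] + stats::rnorm(nb, 0, spec$noise_sd)
    }
    g * vol
  })
}

#' Generate a synthetic control scan
#'
#' Baseline tissue uptake 1.0 inside the brain, modulated by the spec's
#' optional age effect, multiplied by a subject-level global factor and
#' overlaid with independent additive Gaussian voxel noise.
#'
#' @param atlas a `dlb_atlas`.
#' @param age subject age in years (> 0).
#' @param spec a `cohort_spec`.
#' @param seed per-subject seed.
#' @param id subject identifier.
#' @param global_factor optional fixed global uptake factor; if `NULL` it is
#'   drawn from the spec's lognormal distribution.
#' @return a `subject_scan`.
#' @export
make_control <- function(atlas, age, spec = cohort_spec(), seed = 1L,
                         id = "control", global_factor = NULL) {
  stopifnot(inherits(atlas, "dlb_atlas"), age > 0)
  template <- .control_template(atlas, age, spec)
  vol <- .add_subject_noise(template, atlas, spec, seed, global_factor)
  .new_scan(vol, age, id, "control", NA_character_, atlas)
}

#' Generate a synthetic patient scan
#'
#' As [make_control()], but uptake inside each template region is first
#' multiplied by `1 - reduction`. For asymmetric templates the left
#' hemisphere receives the full reduction and the right hemisphere
#' `reduction / asymmetry_factor`. With the same seed and `reduction = 0` the
#' output is identical to the matching control.
#'
#' @inheritParams make_control
#' @param pattern_name one of the template names in `spec$patterns`.
#' @return a `subject_scan`.
#' @export
make_patient <- function(atlas, pattern_name, spec = cohort_spec(), age = 71,
                         seed = 1L, id = pattern_name, global_factor = NULL) {
  stopifnot(inherits(atlas, "dlb_atlas"), age > 0)
  if (!pattern_name %in% names(spec$patterns))
    stop(sprintf("unknown pattern name '%s'", pattern_name))
  pat <- spec$patterns[[pattern_name]]
  template <- .control_template(atlas, age, spec)
  left <- which(atlas$left)
  for (nm in names(pat$rois)) {
    idx <- atlas_region(atlas, nm)
    red <- pat$rois[[nm]]
    if (isTRUE(pat$asymmetric)) {
      li <- idx[idx %in% left]
      ri <- setdiff(idx, li)
      template[li] <- template[li] * (1 - red)
      template[ri] <- template[ri] * (1 - red / spec$asymmetry_factor)
    } else {
      template[idx] <- template[idx] * (1 - red)
    }
  }
  vol <- .add_subject_noise(template, atlas, spec, seed, global_factor)
  .new_scan(vol, age, id, pattern_name, pattern_name, atlas)
}

#' Generate a full synthetic cohort
#'
#' Draws ages (normal, truncated at 18 years), per-subject seeds and scans
#' for the controls and every requested patient group. Fixing `spec$seed`
#' makes the whole cohort, including the metadata table, bit-reproducible.
#'
#' @param spec a `cohort_spec`.
#' @param atlas a `dlb_atlas`.
#' @return list with `controls` (list of `subject_scan`), `patients` (list of
#'   `subject_scan`) and `metadata` (data.frame: subject_id, age, cohort,
#'   pattern, seed).
#' @export
make_cohort <- function(spec = cohort_spec(), atlas = make_atlas()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(atlas, "dlb_atlas"))
  n_pat <- sum(spec$n_patients)
  n_all <- spec$n_controls + n_pat
  plan <- .with_seed(spec$seed, {
    ages_c <- .rtrunc_norm(spec$n_controls, spec$control_age_mean, spec$control_age_sd, 18)
    ages_p <- .rtrunc_norm(n_pat, spec$patient_age_mean, spec$patient_age_sd, 18)
    seeds <- sample.int(.Machine$integer.max - 1L, n_all)
    list(ages_c = ages_c, ages_p = ages_p, seeds = seeds)
  })

  controls <- vector("list", spec$n_controls)
  for (i in seq_len(spec$n_controls)) {
    controls[[i]] <- make_control(atlas, plan$ages_c[i], spec, seed = plan$seeds[i],
                                  id = sprintf("ctrl%03d", i))
  }
  patterns_seq <- rep(names(spec$n_patients), times = spec$n_patients)
  patients <- vector("list", n_pat)
  for (j in seq_len(n_pat)) {
    patients[[j]] <- make_patient(atlas, patterns_seq[j], spec,
                                  age = plan$ages_p[j],
                                  seed = plan$seeds[spec$n_controls + j],
                                  id = sprintf("%s%03d", tolower(patterns_seq[j]), j))
  }
  metadata <- data.frame(
    subject_id = c(vapply(controls, `[[`, "", "id"), vapply(patients, `[[`, "", "id")),
    age = c(plan$ages_c, plan$ages_p),
    cohort = c(rep("control", spec$n_controls), patterns_seq),
    pattern = c(rep(NA_character_, spec$n_controls), patterns_seq),
    seed = plan$seeds,
    stringsAsFactors = FALSE
  )
  list(controls = controls, patients = patients, metadata = metadata)
}

.rtrunc_norm <- function(n, mean, sd, lower) {
  if (n == 0L) return(numeric(0))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
  }
  out
}
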