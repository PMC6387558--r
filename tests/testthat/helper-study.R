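## Shared, lazily built study fixtures.  Heavy objects (the preprocessed
## normative database, the 100-subject phantom cohort with t-maps) are built
## once per test run and reused across files.

.study_cache <- new.env(parent = emptyenv())

study_memo <- function(key, builder) {
  if (!exists(key, envir = .study_cache)) assign(key, builder(), envir = .study_cache)
  get(key, envir = .study_cache)
}

study_atlas <- function() study_memo("atlas", function() make_atlas())

## normative database of 112 controls plus 200 held-out null controls,
## smoothed and scaled once; the analysis mask comes from the database only
study_db <- function() study_memo("db", function() {
  atlas <- study_atlas()
  spec <- cohort_spec(n_controls = 312L, n_patients = c(DLB = 0L), seed = 820731L)
  co <- make_cohort(spec, atlas)
  sm <- lapply(co$controls, smooth_volume)
  mask <- make_brain_mask(sm[1:112])
  sc <- lapply(sm, global_mean_scale, mask = mask)
  list(atlas = atlas, mask = mask,
       cm = control_matrix(sc[1:112], mask),
       ages = vapply(sc[1:112], `[[`, 0, "age"),
       nulls = sc[113:312],
       null_ages = vapply(sc[113:312], `[[`, 0, "age"),
       spec = spec)
})

## full 4-pattern phantom cohort (25 subjects per pattern) run end to end:
## t-maps, thresholded clusters, hallmark profiles, rater labels, vote
study_cohort <- function() study_memo("cohort", function() {
  atlas <- study_atlas()
  db <- study_db()
  spec <- cohort_spec(n_controls = 0L,
                      n_patients = c(DLB = 25L, ADD = 25L, PCA = 25L, PD = 25L),
                      seed = 411017L)
  co <- make_cohort(spec, atlas)
  raters <- default_raters()
  k <- extent_voxels(atlas$voxel_mm)
  template_union <- lapply(spec$patterns, function(p) {
    sort(unique(unlist(lapply(names(p$rois), atlas_region, atlas = atlas))))
  })
  n <- length(co$patients)
  tmaps <- vector("list", n)
  profiles <- vector("list", n)
  rater_labels <- matrix(NA_character_, n, 4)
  voted <- character(n)
  overlap <- logical(n)
  threshold <- NA_real_
  for (i in seq_len(n)) {
    pat <- global_mean_scale(smooth_volume(co$patients[[i]]), db$mask)
    tm <- fwe_threshold(fit_subject_tmap(pat, db$cm, db$mask, ages = db$ages))
    cl <- extract_clusters(tm, k = k)
    hp <- hallmark_profile(pat, cl, atlas)
    rater_labels[i, ] <- vapply(raters, function(r) classify_pattern(hp, r), "")
    voted[i] <- as.character(supermajority_vote(rater_labels[i, ], 3L))
    overlap[i] <- any((cl$labels > 0)[template_union[[pat$cohort]]])
    tmaps[[i]] <- tm
    profiles[[i]] <- hp
    threshold <- tm$threshold
  }
  names(tmaps) <- vapply(co$patients, `[[`, "", "id")
  list(atlas = atlas, spec = spec, truth = vapply(co$patients, `[[`, "", "cohort"),
       tmaps = tmaps, profiles = profiles, rater_labels = rater_labels,
       voted = voted, overlap = overlap, threshold = threshold,
       cis = vapply(profiles, `[[`, 0, "cis"))
})
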