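test_that("the voxel-wise GLM reproduces the classic two-sample t", {
  ## single voxel, no age covariate: textbook pooled-variance t
  ctrl <- c(1.0, 1.2, 0.8, 1.0, 1.0)
  f <- dlbpet:::.tstat_lm(matrix(c(ctrl, 0.5), ncol = 1), cbind(1, c(rep(0, 5), 1)))
  sp2 <- sum((ctrl - mean(ctrl))^2) / 4
  t_classic <- (mean(ctrl) - 0.5) / sqrt(sp2 * (1 / 5 + 1))
  expect_equal(f$t, t_classic, tolerance = 1e-12)
  expect_equal(f$df, 4)

  ## whole maps: GLM without age covariate equals the pooled two-sample
  ## t-map computed independently
  at <- make_atlas(c(24, 24, 24), 6)
  spec <- cohort_spec(seed = 1)
  mask <- at$brain
  ctrls <- lapply(1:12, function(s) make_control(at, 60 + s, spec, seed = s))
  cm <- control_matrix(ctrls, mask)
  pat <- make_patient(at, "DLB", spec, age = 66, seed = 99)
  tm <- fit_subject_tmap(pat, cm, mask, use_age = FALSE)
  expect_equal(tm$t[mask], pooled_tmap(cm, pat$volume[mask]), tolerance = 1e-10)
  expect_equal(tm$df, 11)
})

test_that("a patient equal to the noise-free template yields t = 0 everywhere", {
  at <- make_atlas(c(24, 24, 24), 6)
  spec <- cohort_spec(noise_sd = 0, global_sdlog = 0, seed = 1)
  ctrls <- lapply(1:12, function(s) make_control(at, 55 + s, spec, seed = s, global_factor = 1))
  pat <- make_control(at, 65, spec, seed = 50, global_factor = 1)
  tm <- fit_subject_tmap(pat, ctrls, at$brain)
  expect_true(all(tm$t[at$brain] == 0))
})

test_that("rank-deficient designs fail loudly and grids must match", {
  at <- make_atlas(c(24, 24, 24), 6)
  spec <- cohort_spec(seed = 2)
  ctrls <- lapply(1:12, function(s) make_control(at, 65, spec, seed = s))  # equal ages
  pat <- make_patient(at, "DLB", spec, age = 65, seed = 30)
  expect_error(fit_subject_tmap(pat, ctrls, at$brain, use_age = TRUE), "rank-deficient")
  expect_silent(fit_subject_tmap(pat, ctrls, at$brain, use_age = FALSE))
  bad <- pat; bad$volume <- array(1, c(10, 10, 10))
  expect_error(fit_subject_tmap(bad, ctrls, at$brain, use_age = FALSE), "does not match")
})

test_that("group maps are antisymmetric under label swap and null for duplicated controls", {
  at <- make_atlas(c(24, 24, 24), 6)
  spec <- cohort_spec(seed = 3)
  ga <- lapply(1:12, function(s) make_control(at, 60 + (s %% 5), spec, seed = s))
  gb <- lapply(1:10, function(s) make_control(at, 62 + (s %% 5), spec, seed = 100 + s))
  t1 <- fit_group_tmap(ga, gb, at$brain)
  t2 <- fit_group_tmap(gb, ga, at$brain)
  expect_equal(t1$t[at$brain], -t2$t[at$brain], tolerance = 1e-10)
  expect_equal(t1$df, 22 - 3)

  spec0 <- cohort_spec(noise_sd = 0, global_sdlog = 0, seed = 1)
  ctrls <- lapply(1:12, function(s) make_control(at, 55 + s, spec0, seed = s, global_factor = 1))
  dup <- lapply(1:4, function(s) make_control(at, 60 + s, spec0, seed = s, global_factor = 1))
  tg <- fit_group_tmap(dup, ctrls, at$brain)
  expect_true(all(tg$t[at$brain] == 0))
})

test_that("the age covariate absorbs a linear age effect the plain model flags", {
  spec <- cohort_spec(n_controls = 40L, n_patients = c(DLB = 0L),
                      control_age_mean = 65, control_age_sd = 3,
                      age_slope = -0.015, seed = 550110L)
  co <- make_cohort(spec, study_atlas())
  sm <- lapply(co$controls, smooth_volume)
  mask <- make_brain_mask(sm)
  sc <- lapply(sm, global_mean_scale, mask = mask)
  cm <- control_matrix(sc, mask)
  ages <- vapply(sc, `[[`, 0, "age")
  ## metabolically normal for his age, but 25 years older than the database
  old <- make_control(study_atlas(), 90, spec, seed = 990001L)
  old <- global_mean_scale(smooth_volume(old), mask)
  with_age <- fwe_threshold(fit_subject_tmap(old, cm, mask, ages = ages, use_age = TRUE))
  no_age <- fwe_threshold(fit_subject_tmap(old, cm, mask, use_age = FALSE))
  expect_true(all(abs(with_age$t[mask]) < with_age$threshold))
  expect_gt(sum(no_age$t[mask] >= no_age$threshold), 0)
})

test_that("group maps concentrate suprathreshold voxels on the injected topography", {
  db <- study_db()
  atlas <- study_atlas()
  spec <- cohort_spec(n_controls = 0L, n_patients = c(DLB = 20L), seed = 660042L)
  pats <- lapply(make_cohort(spec, atlas)$patients, function(p)
    global_mean_scale(smooth_volume(p), db$mask))
  tm <- fwe_threshold(fit_group_tmap(pats, db$cm[1:50, ], db$mask,
                                     ages = db$ages[1:50]))
  supra <- !is.na(tm$t) & tm$t >= tm$threshold
  expect_gt(sum(supra), 0)
  ## template regions dilated by one voxel: the smoothing kernel relocates
  ## genuine signal across parcel faces by up to one voxel
  tmpl <- array(FALSE, atlas$dim)
  tmpl[unlist(lapply(names(spec$patterns$DLB$rois), atlas_region, atlas = atlas))] <- TRUE
  for (ax in 1:3) tmpl <- dlbpet:::.dilate_axis(tmpl, ax, 1L)
  expect_gte(sum(supra & tmpl) / sum(supra), 0.90)
})

test_that("the Bonferroni threshold matches an independent CDF inversion", {
  expect_equal(bonferroni_threshold(0.05, 1, 20), qt(0.95, 20))
  ## root-find the Student CDF rather than call qt
  oracle <- uniroot(function(t) pt(t, 110, lower.tail = FALSE) - 0.05 / 30000,
                    c(0, 50), tol = 1e-12)$root
  expect_equal(bonferroni_threshold(0.05, 30000, 110), oracle, tolerance = 1e-9)
  expect_true(bonferroni_threshold(0.05, 2000, 50) > bonferroni_threshold(0.05, 1000, 50))
  expect_true(bonferroni_threshold(0.01, 1000, 50) > bonferroni_threshold(0.05, 1000, 50))
  expect_error(bonferroni_threshold(0.05, 100, 0), "positive")
})

test_that("cluster extraction honours extent, connectivity and the flood-fill oracle", {
  d <- c(24, 24, 24)
  mask <- array(TRUE, d)
  mk_tmap <- function(tvol) {
    tm <- structure(list(t = tvol, df = 20, mask = mask, threshold = 0.5),
                    class = "tmap")
    tm
  }
  tv <- array(0, d)
  tv[2, 1:9, 2] <- 1    # 9-voxel line
  tv[10, 1:10, 10] <- 1 # 10-voxel line
  cl <- extract_clusters(mk_tmap(tv), t_threshold = 0.5, k = 10)
  expect_equal(cl$sizes, 10L)
  expect_equal(sum(cl$labels > 0), 10L)
  cl2 <- extract_clusters(mk_tmap(tv), t_threshold = 0.5, k = 10, strict_gt = TRUE)
  expect_length(cl2$sizes, 0L)
  none <- extract_clusters(mk_tmap(array(0, d)), t_threshold = 0.5, k = 1)
  expect_length(none$sizes, 0L)

  set.seed(8)
  rnd <- array(runif(prod(d)) < 0.25, d)
  for (conn in c(6L, 18L, 26L)) {
    ours <- label_components(rnd, conn)
    oracle <- ff_label(rnd, conn)
    ## same partition: label images must be a relabelling of each other
    key <- paste(ours[rnd], oracle[rnd])
    expect_equal(length(unique(key)), max(oracle))
    expect_equal(max(ours), max(oracle))
  }
})
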