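test_that("atlas regions are disjoint, brain-contained, mirror-symmetric and deterministic", {
  at <- make_atlas(c(40, 48, 40), 4)
  all_regions <- c(at$roi, at$aux)
  expect_length(at$roi, 14L)
  idx <- unlist(all_regions, use.names = FALSE)
  expect_equal(anyDuplicated(idx), 0L)
  expect_true(all(at$brain[idx]))
  expect_true(all(vapply(at$roi, length, 0L) >= 20L))

  mirror <- function(i) {
    ijk <- arrayInd(i, at$dim)
    ijk[, 1] <- at$dim[1] + 1L - ijk[, 1]
    sort(ijk[, 1] + at$dim[1] * (ijk[, 2] - 1) + at$dim[1] * at$dim[2] * (ijk[, 3] - 1))
  }
  for (nm in names(at$roi)) expect_equal(mirror(at$roi[[nm]]), at$roi[[nm]])
  expect_equal(mirror(which(at$left)), sort(which(at$right)))
  expect_equal(sum(at$left & at$right), 0L)

  expect_identical(at, make_atlas(c(40, 48, 40), 4))
  expect_error(make_atlas(c(8, 8, 8), 4), "cannot place")
  small <- make_atlas(c(24, 24, 24), 6)
  expect_true(all(vapply(small$roi, length, 0L) >= 20L))
})

test_that("control scans are template plus scaled noise", {
  at <- make_atlas(c(24, 24, 24), 6)
  noiseless <- cohort_spec(noise_sd = 0, global_sdlog = 0, seed = 1)
  c0 <- make_control(at, 65, noiseless, seed = 5, global_factor = 1)
  tmpl <- array(0, at$dim); tmpl[at$brain] <- 1
  expect_equal(c0$volume, tmpl)

  spec <- cohort_spec(noise_sd = 0.05, global_sdlog = 0, seed = 1)
  c1 <- make_control(at, 65, spec, seed = 5, global_factor = 1)
  c2 <- make_control(at, 65, spec, seed = 5, global_factor = 2)
  expect_equal(c2$volume, 2 * c1$volume)
  c3 <- make_control(at, 65, spec, seed = 6, global_factor = 1)
  expect_false(identical(c1$volume, c3$volume))
  expect_equal(c1$volume[!at$brain], c3$volume[!at$brain])  # differ only in brain noise

  ## template recoverable as the voxel-wise mean; error shrinks as 1/sqrt(N)
  n <- 200
  acc <- array(0, at$dim)
  for (s in seq_len(n)) acc <- acc + make_control(at, 65, spec, seed = s, global_factor = 1)$volume
  expect_lt(max(abs(acc / n - tmpl)), 5 * 0.05 / sqrt(n))
})

test_that("patient scans apply the template reductions exactly", {
  at <- make_atlas(c(24, 24, 24), 6)
  spec <- cohort_spec(noise_sd = 0, global_sdlog = 0, seed = 1)
  p <- make_patient(at, "DLB", spec, age = 70, seed = 3, global_factor = 1)
  occ <- atlas_region(at, "occipital_mid")
  expect_equal(mean(p$volume[occ]), 0.75)          # 25% reduction on uptake 1.0
  expect_equal(mean(p$volume[atlas_region(at, "posterior_cingulate")]), 1)  # spared

  ## zero reduction reproduces the control bit for bit (same seed)
  spec0 <- spec
  spec0$patterns$DLB$rois[] <- 0
  noisy <- cohort_spec(noise_sd = 0.05, seed = 1)
  noisy0 <- noisy; noisy0$patterns$DLB$rois[] <- 0
  p0 <- make_patient(at, "DLB", noisy0, age = 70, seed = 9)
  c0 <- make_control(at, 70, noisy, seed = 9)
  expect_identical(p0$volume, c0$volume)

  ## asymmetric pattern: left reduction = factor x right reduction
  aspec <- cohort_spec(noise_sd = 0, global_sdlog = 0, asymmetry_factor = 2, seed = 1)
  pp <- make_patient(at, "PCA", aspec, age = 70, seed = 3, global_factor = 1)
  li <- intersect(occ, which(at$left)); ri <- intersect(occ, which(at$right))
  expect_equal(1 - mean(pp$volume[li]), 2 * (1 - mean(pp$volume[ri])))
  expect_error(make_patient(at, "nope", spec), "unknown pattern")
})

test_that("cohorts are reproducible with ages matching the normative database", {
  at <- make_atlas(c(24, 24, 24), 6)
  spec <- cohort_spec(n_controls = 112L, n_patients = c(DLB = 2L), seed = 42)
  co1 <- make_cohort(spec, at)
  co2 <- make_cohort(spec, at)
  expect_identical(co1$metadata, co2$metadata)
  expect_identical(co1$controls[[50]]$volume, co2$controls[[50]]$volume)
  expect_length(co1$controls, 112L)
  ages <- co1$metadata$age[co1$metadata$cohort == "control"]
  expect_lt(abs(mean(ages) - 64.68), 3 * 9.35 / sqrt(112))
  expect_true(all(ages >= 18))

  empty <- make_cohort(cohort_spec(n_controls = 3L, n_patients = c(DLB = 0L), seed = 1), at)
  expect_length(empty$patients, 0L)
  expect_equal(nrow(empty$metadata), 3L)
})

test_that("cohort_spec rejects invalid effect sizes", {
  bad <- default_patterns()
  bad$DLB$rois[1] <- 1.2
  expect_error(cohort_spec(patterns = bad), "\\[0, 1\\)")
})
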