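make_cluster_set <- function(labels, k = 1L) {
  structure(list(labels = labels, sizes = tabulate(labels[labels > 0]),
                 k = k, connectivity = 18L, threshold = 1),
            class = "cluster_set")
}

test_that("the cingulate island sign is a scale-invariant regional ratio", {
  at <- make_atlas(c(24, 24, 24), 6)
  v <- array(0, at$dim); v[at$brain] <- 1
  expect_equal(cingulate_island_sign(v, at), 0.5)     # uniform: 1 / (1 + 1)
  v2 <- v
  v2[at$roi$posterior_cingulate] <- 1.0
  v2[at$roi$precuneus] <- 0.6
  v2[at$roi$cuneus] <- 0.6
  expect_equal(cingulate_island_sign(v2, at), 1 / 1.2)
  expect_equal(cingulate_island_sign(7 * v2, at), cingulate_island_sign(v2, at))
  expect_equal(cingulate_island_sign(global_mean_scale(v2, at$brain, 3), at),
               cingulate_island_sign(v2, at))
  expect_error(cingulate_island_sign(0 * v, at), "denominator")
})

test_that("ROI involvement follows the fraction rule monotonically", {
  at <- make_atlas(c(24, 24, 24), 6)
  lab <- array(0L, at$dim)
  empty <- make_cluster_set(lab)
  expect_false(roi_involvement(empty, at, "occipital"))
  expect_false(roi_involvement(empty, at, "dlpfc"))

  lab2 <- lab; lab2[at$roi$cuneus] <- 1L      # cluster exactly covering the cuneus
  covered <- make_cluster_set(lab2)
  expect_true(roi_involvement(covered, at, "occipital", 0.02))
  frac <- length(at$roi$cuneus) / length(at$composites$occipital)
  expect_true(roi_involvement(covered, at, "occipital", frac))
  expect_false(roi_involvement(covered, at, "occipital", frac + 1e-6))
  expect_error(roi_involvement(covered, at, "not_a_roi"), "unknown ROI")
})

test_that("the asymmetry index counts hemispheric suprathreshold voxels", {
  at <- make_atlas(c(24, 24, 24), 6)
  lab <- array(0L, at$dim)
  expect_equal(asymmetry_index(make_cluster_set(lab), at)$ai, 0)
  expect_true(asymmetry_index(make_cluster_set(lab), at)$symmetric)

  li <- which(at$left); ri <- which(at$right)
  lab[li[1:900]] <- 1L; lab[ri[1:100]] <- 1L
  a <- asymmetry_index(make_cluster_set(lab), at)
  expect_equal(a$ai, 0.8)
  expect_false(a$symmetric)

  ## mirror flip leaves the index unchanged
  flip <- lab[at$dim[1]:1, , ]
  expect_equal(asymmetry_index(make_cluster_set(flip), at)$ai, a$ai)
})

test_that("the ROC cutoff maximizes Youden's J and the AUC matches pair counting", {
  r <- cis_cutoff(c(0.9, 0.85), c(0.5, 0.6))
  expect_equal(r$auc, 1)
  expect_equal(r$cutoff, 0.725)
  same <- cis_cutoff(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$auc, 0.5)
  set.seed(77)
  a <- rnorm(20, 1); b <- rnorm(20)
  r2 <- cis_cutoff(a, b)
  expect_equal(r2$auc, pair_count_auc(a, b))
  expect_equal(r2$sensitivity, mean(a >= r2$cutoff))
  expect_equal(r2$specificity, mean(b < r2$cutoff))
})

test_that("synthetic cohorts separate DLB from AD on CIS and occipital involvement", {
  sc <- study_cohort()
  dlb <- sc$truth == "DLB"; add <- sc$truth == "ADD"
  expect_gt(mean(sc$cis[dlb]), mean(sc$cis[add]))
  roc <- cis_cutoff(sc$cis[dlb], sc$cis[add])
  expect_gte(roc$auc, 0.9)

  occ <- vapply(sc$profiles, `[[`, TRUE, "occipital")
  expect_gte(mean(occ[dlb]), 0.95)
  expect_lte(mean(occ[add]), 0.05)
})
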