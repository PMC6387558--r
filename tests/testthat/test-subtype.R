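test_that("feature matrix rows are per-ROI mean t values", {
  at <- make_atlas(c(24, 24, 24), 6)
  mask <- at$brain
  mk <- function(val) {
    tv <- array(NA_real_, at$dim); tv[mask] <- val
    structure(list(t = tv, df = 20, mask = mask), class = "tmap")
  }
  fm <- build_feature_matrix(list(a = mk(0), b = mk(3)), at)
  expect_equal(dim(fm), c(2L, 14L))
  expect_true(all(fm["a", ] == 0))
  expect_true(all(fm["b", ] == 3))
  expect_equal(colnames(fm), at$roi_names)
})

test_that("PCA reduction reproduces the eigendecomposition and reconstructs", {
  set.seed(12)
  x <- matrix(rnorm(90), 30, 3)
  p <- pca_reduce(x, 0.8)
  ev <- eigen(cov(scale(x)))$values
  expect_equal(p$explained, ev / sum(ev), tolerance = 1e-12)
  rk1 <- outer(rnorm(10), c(1, 2, 3))
  expect_equal(pca_reduce(rk1, 0.99, scale = FALSE)$ncomp, 1L)
  full <- pca_reduce(x, 1, scale = FALSE)
  rec <- full$scores %*% t(full$fit$rotation)
  expect_lt(max(abs(rec - scale(x, scale = FALSE))), 1e-9)
  expect_error(pca_reduce(x, 1.5), "variance_target")
  expect_error(pca_reduce(x[1:2, ], 0.8), "nrow")
})

test_that("Chebyshev-Ward agglomeration matches hclust and the exhaustive oracle", {
  set.seed(21)
  x <- matrix(rnorm(16), 8, 2)
  ours <- hcluster_chebyshev_ward(x)
  bf <- bf_chebyshev_ward(x)
  expect_equal(ours$height, bf$height, tolerance = 1e-12)
  ## same merge partition sequence (coding of intermediate ids may differ)
  part_seq <- function(merge, n) {
    mem <- lapply(seq_len(n), identity)
    clusters <- as.list(-(seq_len(n)))
    out <- list()
    groups <- as.list(seq_len(n))
    for (s in seq_len(nrow(merge))) {
      get_m <- function(v) if (v < 0) -v else out[[v]]
      out[[s]] <- sort(c(get_m(merge[s, 1]), get_m(merge[s, 2])))
    }
    out
  }
  expect_equal(part_seq(ours$merge, 8), part_seq(bf$merge, 8))

  ref <- hclust(dist(x, method = "maximum"), method = "ward.D2")
  expect_equal(sort(ours$height), sort(ref$height), tolerance = 1e-12)
  expect_true(all(diff(ours$height) >= -1e-12))   # Ward monotonicity

  ## identical points merge first at height zero
  y <- rbind(c(0, 0), c(5, 5), c(0, 0), c(9, 1))
  hy <- hcluster_chebyshev_ward(y)
  expect_equal(hy$height[1], 0)
  expect_equal(hy$merge[1, ], c(-3L, -1L))
})

test_that("cutting recovers planted blobs and is order-equivariant", {
  set.seed(31)
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 10), 20))
  hc <- hcluster_chebyshev_ward(x)
  cl <- cut_tree(hc, 2)
  expect_equal(length(unique(cl[1:20])), 1L)
  expect_equal(length(unique(cl[21:40])), 1L)
  expect_true(cl[1] != cl[21])
  expect_equal(cut_tree(hc, 1), rep(1L, 40))
  expect_equal(sort(unique(cut_tree(hc, 40))), 1:40)
  expect_error(cut_tree(hc, 0), "invalid k")

  perm <- sample(40)
  clp <- cut_tree(hcluster_chebyshev_ward(x[perm, ]), 2)
  clp_orig <- clp[match(1:40, perm)]   # back to original subject order
  expect_equal(clp_orig == clp_orig[1], cl == cl[1])  # same partition

  sizes <- table(cut_tree(hc, 2))
  expect_true(sizes[1] >= sizes[2])   # label 1 is the larger subgroup
})

test_that("Ward heights are monotone on random instances", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- matrix(rnorm(14 * 4), 14, 4)
    hc <- hcluster_chebyshev_ward(x)
    expect_true(all(diff(hc$height) >= -1e-10))
  }
})

test_that("subgroup comparison reproduces the published chi-squares and handles types", {
  expect_equal(round(chi2_from_rates(0.935, 31, 0.634, 41)$statistic, 3), 8.887)
  expect_equal(round(chi2_from_rates(0.846, 13, 0.348, 23)$statistic, 3), 8.276)

  labels <- rep(c(1, 2), each = 10)
  clin <- data.frame(vh = c(rep(1, 9), 0, rep(c(0, 1), 5)),
                     mmse = c(rnorm(10, 20, 2), rnorm(10, 16, 2)),
                     flat = rep(1, 20))
  out <- subgroup_compare(labels, clin)
  expect_equal(out$type, c("binary", "continuous", "binary"))
  expect_equal(out$statistic[out$feature == "flat"], 0)
  oracle <- suppressWarnings(chisq.test(table(labels, clin$vh), correct = FALSE))
  expect_equal(out$statistic[out$feature == "vh"], unname(oracle$statistic))
})
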