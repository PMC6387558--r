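## Independent oracle implementations used only to check the package code.

## stack-based flood fill, one component at a time
ff_label <- function(mask, connectivity = 18L) {
  n <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  manh <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- switch(as.character(connectivity),
                 "6" = offs[manh == 1, ], "18" = offs[manh <= 2, ], "26" = offs)
  lab <- array(0L, n)
  nextlab <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    nextlab <- nextlab + 1L
    stack <- start
    lab[start] <- nextlab
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      ijk <- arrayInd(v, n)
      for (r in seq_len(nrow(offs))) {
        p <- ijk + c(offs$dx[r], offs$dy[r], offs$dz[r])
        if (any(p < 1) || any(p > n)) next
        li <- p[1] + n[1] * (p[2] - 1) + n[1] * n[2] * (p[3] - 1)
        if (mask[li] && lab[li] == 0L) { lab[li] <- nextlab; stack <- c(stack, li) }
      }
    }
  }
  lab
}

## exhaustive Lance-Williams Ward agglomeration on squared Chebyshev
## dissimilarities, recomputing a fresh dissimilarity matrix at each step
bf_chebyshev_ward <- function(x) {
  n <- nrow(x)
  cheb <- function(a, b) max(abs(a - b))
  members <- as.list(seq_len(n))
  ids <- -(seq_len(n))
  d2 <- outer(seq_len(n), seq_len(n),
              Vectorize(function(i, j) cheb(x[i, ], x[j, ])^2))
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    m <- length(members)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      if (d2[i, j] < best[1]) best <- c(d2[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    heights[s] <- sqrt(best[1])
    merges[s, ] <- sort(c(ids[i], ids[j]))
    ni <- length(members[[i]]); nj <- length(members[[j]])
    keep <- setdiff(seq_len(m), c(i, j))
    newd <- d2[keep, keep, drop = FALSE]
    extra <- numeric(length(keep))
    for (a in seq_along(keep)) {
      k <- keep[a]; nk <- length(members[[k]])
      extra[a] <- ((ni + nk) * d2[k, i] + (nj + nk) * d2[k, j] - nk * d2[i, j]) /
        (ni + nj + nk)
    }
    d2 <- rbind(cbind(newd, extra), c(extra, 0))
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
    ids <- c(ids[keep], s)
  }
  list(merge = merges, height = heights)
}

## textbook pooled-variance two-sample t at every voxel (controls vs one
## patient), vectorized independently of the GLM code path
pooled_tmap <- function(cm, pvec) {
  n1 <- nrow(cm)
  mbar <- colMeans(cm)
  ss <- colSums(sweep(cm, 2, mbar)^2)
  sp2 <- ss / (n1 + 1 - 2)
  (mbar - pvec) / sqrt(sp2 * (1 / n1 + 1))
}

## Mann-Whitney AUC by explicit pair counting
pair_count_auc <- function(pos, neg) {
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}
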