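# Independent brute-force oracles used to validate the selection module.
# Deliberately written as plain nested loops, separate from the package's
# vectorized implementations.

oracle_bin <- function(x, bins) {
  lo <- min(x); hi <- max(x)
  if (lo == hi) return(rep(1L, length(x)))
  out <- integer(length(x))
  for (i in seq_along(x)) {
    b <- floor((x[i] - lo) / (hi - lo) * bins) + 1
    out[i] <- as.integer(min(b, bins))
  }
  out
}

oracle_mi <- function(bx, by, bins) {
  n <- length(bx)
  counts <- matrix(0, bins, bins)
  for (i in seq_len(n)) counts[bx[i], by[i]] <- counts[bx[i], by[i]] + 1
  px <- rowSums(counts) / n
  py <- colSums(counts) / n
  mi <- 0
  for (a in seq_len(bins)) for (b in seq_len(bins)) {
    p <- counts[a, b] / n
    if (p > 0 && px[a] > 0 && py[b] > 0) mi <- mi + p * log(p / (px[a] * py[b]))
  }
  mi
}

# Greedy mRMR (MID scheme), lexicographic tie-break, constants last.
oracle_mrmr <- function(table, target, k, bins = 16) {
  feats <- sort(setdiff(names(table)[sapply(table, is.numeric)],
                        c("sbp", "dbp", "pulse_index")))
  by <- oracle_bin(table[[target]], bins)
  bx <- lapply(table[feats], oracle_bin, bins = bins)
  rel <- sapply(feats, function(f) {
    if (length(unique(table[[f]])) == 1) -Inf else oracle_mi(bx[[f]], by, bins)
  })
  sel <- character(0)
  for (step in seq_len(k)) {
    cand <- setdiff(feats, sel)
    scores <- sapply(cand, function(f) {
      if (is.infinite(rel[[f]])) return(-Inf)
      if (length(sel) == 0) return(rel[[f]])
      red <- 0
      for (s in sel) red <- red + oracle_mi(bx[[f]], bx[[s]], bins)
      rel[[f]] - red / length(sel)
    })
    best <- cand[order(-scores, cand)][1]
    sel <- c(sel, best)
  }
  sel
}

# RReliefF update equations with explicit loops; expects distinct rows and
# n_iterations covering every row.
oracle_rrelieff <- function(X, y, n_neighbors, sigma = 5) {
  n <- nrow(X); p <- ncol(X)
  rngs <- apply(X, 2, function(col) max(col) - min(col))
  rngs[rngs == 0] <- Inf
  Xn <- X
  for (j in seq_len(p)) Xn[, j] <- X[, j] / rngs[j]
  y_rng <- max(y) - min(y)
  w <- exp(-(seq_len(n_neighbors) / sigma)^2)
  w <- w / sum(w)
  ndc <- 0; nda <- numeric(p); ndcda <- numeric(p)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sum(abs(Xn[j, ] - Xn[i, ]))
    d[i] <- Inf
    d[d == 0] <- Inf
    nb <- order(d)[seq_len(min(n_neighbors, sum(is.finite(d))))]
    for (r in seq_along(nb)) {
      q <- nb[r]
      dy <- abs(y[q] - y[i]) / y_rng
      ndc <- ndc + w[r] * dy
      for (j in seq_len(p)) {
        da <- abs(Xn[q, j] - Xn[i, j])
        nda[j] <- nda[j] + w[r] * da
        ndcda[j] <- ndcda[j] + w[r] * dy * da
      }
    }
  }
  ndcda / ndc - (nda - ndcda) / (n - ndc)
}
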