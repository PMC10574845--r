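# Feature selection: greedy mRMR ranking (mutual-information difference
# scheme) and RReliefF importance scores, plus the importance-threshold
# rule that fixes how many features enter the regressors.

# Equal-width binning into `bins` levels; constant columns map to bin 1.
.equal_width_bin <- function(x, bins) {
  r <- range(x)
  if (!all(is.finite(r)) || r[1] == r[2]) return(rep(1L, length(x)))
  b <- pmin(floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L, bins)
  as.integer(b)
}

# Mutual information (nats) of two integer bin vectors.
.mi_binned <- function(bx, by, bins) {
  n <- length(bx)
  joint <- tabulate((bx - 1L) * bins + by, nbins = bins * bins) / n
  px <- tabulate(bx, nbins = bins) / n
  py <- tabulate(by, nbins = bins) / n
  pxy <- matrix(joint, nrow = bins, byrow = TRUE)   # rows = bx, cols = by
  pxpy <- outer(px, py)
  ok <- pxy > 0 & pxpy > 0
  sum(pxy[ok] * log(pxy[ok] / pxpy[ok]))
}

#' Greedy mRMR feature ranking
#'
#' Minimum-redundancy maximum-relevance ordering for a continuous target.
#' Relevance and redundancy are mutual information estimated by
#' equal-width binning; at each step the feature maximizing
#' `MI(feature, target) - mean(MI(feature, selected))` is appended
#' (mutual-information difference scheme). Ties break lexicographically by
#' feature name; constant columns score `-Inf` and rank last.
#'
#' @param table Feature table (data frame).
#' @param target `"sbp"` or `"dbp"` (any numeric column).
#' @param k Number of features to rank (clamped to the number of features
#'   with a warning).
#' @param bins Number of equal-width bins (default 16).
#' @return List of class `ranking_result`: `method`, `features` (ordered
#'   names), `scores` (greedy mRMR score at selection time), `k_selected`.
#' @export
mrmr_rank <- function(table, target = "sbp", k = 20, bins = 16) {
  feats <- feature_columns(table)
  if (length(feats) < 2) stop("need at least 2 features")
  y <- table[[target]]
  if (is.null(y)) stop("unknown target column '", target, "'")
  if (stats::sd(y) == 0) stop("constant target")
  if (k > length(feats)) {
    warning("k clamped to ", length(feats), " available features")
    k <- length(feats)
  }
  by <- .equal_width_bin(y, bins)
  bx <- lapply(table[feats], .equal_width_bin, bins = bins)
  constant <- vapply(table[feats], function(col) stats::sd(col) == 0, logical(1))
  rel <- vapply(feats, function(f) {
    if (constant[[f]]) -Inf else .mi_binned(bx[[f]], by, bins)
  }, numeric(1))

  ord <- feats[order(-rel, feats)]
  selected <- character(0)
  scores <- numeric(0)
  red_cache <- list()
  remaining <- ord
  for (step in seq_len(k)) {
    if (step == 1) {
      best <- remaining[1]                      # max relevance, ties by name
      best_score <- rel[[best]]
    } else {
      cand_scores <- vapply(remaining, function(f) {
        if (is.infinite(rel[[f]])) return(-Inf)
        red <- mean(vapply(selected, function(s)
          .mi_binned(bx[[f]], bx[[s]], bins), numeric(1)))
        rel[[f]] - red
      }, numeric(1))
      o <- order(-cand_scores, remaining)
      best <- remaining[o[1]]
      best_score <- cand_scores[o[1]]
    }
    selected <- c(selected, best)
    scores <- c(scores, best_score)
    remaining <- setdiff(remaining, best)
  }
  structure(list(method = "mrmr", features = selected, scores = scores,
                 k_selected = length(selected)),
            class = "ranking_result")
}

#' RReliefF feature importance for regression
#'
#' Standard regressional ReliefF: for each of `n_iterations` sampled
#' instances, the `n_neighbors` nearest neighbors (Manhattan distance on
#' range-normalized features) update the probability estimates of a
#' changed prediction (`N_dC`), a changed attribute (`N_dA`), and both
#' (`N_dC_dA`), with exponentially rank-decayed neighbor weights
#' (`exp(-(rank/sigma)^2)`, normalized). The weight of attribute A is
#' `N_dC_dA/N_dC - (N_dA - N_dC_dA)/(m - N_dC)`, always in `[-1, 1]`.
#'
#' @param table Feature table.
#' @param target Target column name.
#' @param n_neighbors Neighbors per sampled instance (default 10).
#' @param n_iterations Sampled instances (default `min(n, 5000)`).
#' @param sigma Rank-decay scale of the neighbor weights (default 5).
#' @param seed Integer seed (sampling of instances).
#' @return `ranking_result` with features ordered by decreasing score.
#' @export
rrelieff_scores <- function(table, target = "sbp", n_neighbors = 10,
                            n_iterations = NULL, sigma = 5, seed = 1L) {
  feats <- feature_columns(table)
  y <- table[[target]]
  n <- length(y)
  if (n < n_neighbors + 1) stop("need at least n_neighbors + 1 rows")
  X <- as.matrix(table[feats])
  rngs <- apply(X, 2, function(col) diff(range(col)))
  y_rng <- diff(range(y))
  if (y_rng == 0 || all(rngs == 0)) {
    sc <- stats::setNames(rep(0, length(feats)), feats)
    return(structure(list(method = "rrelieff", features = feats,
                          scores = sc, k_selected = 0L),
                     class = "ranking_result"))
  }
  rngs[rngs == 0] <- Inf                  # constant features: zero diff
  Xn <- sweep(X, 2, rngs, "/")
  # exact duplicate observations carry no contrast information and would
  # displace genuine neighbors; collapse them so the estimate is invariant
  # to row duplication
  key <- do.call(paste, c(as.data.frame(Xn), list(y)))
  uniq <- !duplicated(key)
  Xn <- Xn[uniq, , drop = FALSE]
  y <- y[uniq]
  n <- length(y)
  if (n < n_neighbors + 1) stop("need at least n_neighbors + 1 distinct rows")
  if (is.null(n_iterations)) n_iterations <- min(n, 5000L)

  w_rank <- exp(-(seq_len(n_neighbors) / sigma)^2)
  w_rank <- w_rank / sum(w_rank)

  picks <- .with_seed(seed, function() {
    if (n_iterations >= n) seq_len(n) else sample.int(n, n_iterations)
  })
  ndc <- 0
  nda <- numeric(length(feats))
  ndcda <- numeric(length(feats))
  for (i in picks) {
    d <- rowSums(abs(sweep(Xn, 2, Xn[i, ], "-")))
    d[i] <- Inf
    d[d == 0] <- Inf        # exact duplicates carry no contrast information
    n_avail <- sum(is.finite(d))
    if (n_avail == 0) next
    nb <- order(d)[seq_len(min(n_neighbors, n_avail))]
    wr <- w_rank[seq_along(nb)]
    dy <- abs(y[nb] - y[i]) / y_rng
    ndc <- ndc + sum(wr * dy)
    dA <- abs(sweep(Xn[nb, , drop = FALSE], 2, Xn[i, ], "-"))
    nda <- nda + colSums(wr * dA)
    ndcda <- ndcda + colSums((wr * dy) * dA)
  }
  m <- length(picks)
  scores <- if (ndc <= 0 || m - ndc <= 0) rep(0, length(feats))
            else ndcda / ndc - (nda - ndcda) / (m - ndc)
  names(scores) <- feats
  ord <- order(-scores, feats)
  structure(list(method = "rrelieff", features = feats[ord],
                 scores = scores[ord], k_selected = length(feats)),
            class = "ranking_result")
}

#' Number of significant features by importance threshold
#'
#' Counts the features whose importance score strictly exceeds the
#' threshold (default 0.001); lower scores are treated as not
#' significantly related to the target.
#'
#' @param ranking A `ranking_result` (typically RReliefF).
#' @param threshold Strict lower bound on the score.
#' @return Integer count; warns when zero.
#' @export
choose_k <- function(ranking, threshold = 0.001) {
  stopifnot(inherits(ranking, "ranking_result"))
  k <- sum(ranking$scores > threshold)
  if (k == 0) warning("no feature scores above the threshold")
  k
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("%s ranking: %d features\n", x$method, length(x$features)))
  top <- utils::head(seq_along(x$features), 10)
  for (i in top) cat(sprintf("  %2d. %-32s %+.4f\n", i, x$features[i],
                             x$scores[i]))
  invisible(x)
}
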