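#' First-order accumulated local effects
#'
#' The Apley--Zhu first-order ALE estimator: the feature range is divided at
#' sample quantiles; within each bin the local effect is the mean prediction
#' difference obtained by moving every observation in the bin from the lower
#' to the upper bin edge (all other features held at their observed values);
#' local effects are accumulated across bins and centered so that the
#' data-weighted mean effect is zero.
#'
#' @param model A fitted model ([fit_model()] result, a `randomForest`, or a
#'   plain prediction function of a feature data.frame).
#' @param data Data.frame of feature values at which effects are estimated.
#' @param feature Feature name.
#' @param n_bins Number of quantile bins (collapsed to the distinct values
#'   when the feature has fewer).
#' @return Data.frame with `x` (bin edges) and `ale`; attribute `n` gives
#'   per-bin counts. A constant feature yields a flat zero profile with a
#'   warning.
#' @export
ale_first_order <- function(model, data, feature, n_bins = 20) {
  pf <- as_predict_fun(model)
  assert_that(feature %in% names(data), "feature '%s' not in data", feature)
  x <- data[[feature]]
  edges <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                  names = FALSE))
  K <- length(edges) - 1L
  if (K < 1L) {
    warning(sprintf("feature '%s' is constant; ALE is identically zero", feature))
    return(data.frame(x = edges, ale = 0))
  }
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  lo <- data; lo[[feature]] <- edges[bin]
  hi <- data; hi[[feature]] <- edges[bin + 1L]
  diffs <- pf(hi) - pf(lo)
  d <- vapply(seq_len(K), function(k) {
    in_k <- bin == k
    if (any(in_k)) mean(diffs[in_k]) else 0
  }, numeric(1))
  n_k <- tabulate(bin, nbins = K)
  g <- c(0, cumsum(d))
  center <- sum(n_k * (g[-(K + 1L)] + g[-1L]) / 2) / sum(n_k)
  out <- data.frame(x = edges, ale = g - center)
  attr(out, "n") <- n_k
  out
}

#' Second-order accumulated local effects
#'
#' The Apley--Zhu second-order estimator for a feature pair: mean cross
#' differences of predictions over a quantile grid are doubly accumulated,
#' the accumulated first-order (row/column) effects are subtracted, and the
#' surface is centered to data-weighted mean zero. Empty grid cells borrow
#' the cross difference of the nearest non-empty cell and are flagged.
#'
#' @param model As in [ale_first_order()].
#' @param data Data.frame of feature values.
#' @param feature_i,feature_j The feature pair.
#' @param n_bins Quantile bins per feature (default 10).
#' @return List with `x_i`, `x_j` (bin edges), `ale` (matrix over the edge
#'   grid), `filled` (matrix flagging interpolated empty cells), `n` (cell
#'   counts).
#' @export
ale_second_order <- function(model, data, feature_i, feature_j, n_bins = 10) {
  pf <- as_predict_fun(model)
  assert_that(all(c(feature_i, feature_j) %in% names(data)),
              "features not in data")
  xi <- data[[feature_i]]; xj <- data[[feature_j]]
  ei <- unique(stats::quantile(xi, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE))
  ej <- unique(stats::quantile(xj, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE))
  K1 <- length(ei) - 1L; K2 <- length(ej) - 1L
  assert_that(K1 >= 1 && K2 >= 1, "both features must be non-constant")
  bi <- findInterval(xi, ei, rightmost.closed = TRUE, all.inside = TRUE)
  bj <- findInterval(xj, ej, rightmost.closed = TRUE, all.inside = TRUE)

  corner <- function(i_edge, j_edge) {
    nd <- data
    nd[[feature_i]] <- i_edge
    nd[[feature_j]] <- j_edge
    pf(nd)
  }
  cross <- corner(ei[bi + 1L], ej[bj + 1L]) - corner(ei[bi + 1L], ej[bj]) -
    corner(ei[bi], ej[bj + 1L]) + corner(ei[bi], ej[bj])

  d <- matrix(NA_real_, K1, K2)
  n_cell <- matrix(0L, K1, K2)
  for (a in seq_len(K1)) {
    for (b in seq_len(K2)) {
      in_cell <- bi == a & bj == b
      n_cell[a, b] <- sum(in_cell)
      if (any(in_cell)) d[a, b] <- mean(cross[in_cell])
    }
  }
  filled <- is.na(d)
  if (any(filled)) {
    nonempty <- which(!filled, arr.ind = TRUE)
    for (idx in which(filled)) {
      a <- (idx - 1L) %% K1 + 1L; b <- (idx - 1L) %/% K1 + 1L
      dd <- (nonempty[, 1] - a)^2 + (nonempty[, 2] - b)^2
      nn <- nonempty[which.min(dd), , drop = FALSE]
      d[a, b] <- d[nn[1], nn[2]]
    }
  }
  # double accumulation
  FF <- matrix(0, K1 + 1L, K2 + 1L)
  for (a in seq_len(K1)) {
    for (b in seq_len(K2)) {
      FF[a + 1L, b + 1L] <- d[a, b] + FF[a, b + 1L] + FF[a + 1L, b] - FF[a, b]
    }
  }
  # subtract accumulated first-order (row/column) effects
  n_row <- rowSums(n_cell); n_col <- colSums(n_cell)
  t1 <- vapply(seq_len(K1), function(a) {
    if (n_row[a] == 0) return(0)
    sum(n_cell[a, ] * ((FF[a + 1L, -1L] - FF[a, -1L]) +
                       (FF[a + 1L, -(K2 + 1L)] - FF[a, -(K2 + 1L)])) / 2) / n_row[a]
  }, numeric(1))
  t2 <- vapply(seq_len(K2), function(b) {
    if (n_col[b] == 0) return(0)
    sum(n_cell[, b] * ((FF[-1L, b + 1L] - FF[-1L, b]) +
                       (FF[-(K1 + 1L), b + 1L] - FF[-(K1 + 1L), b])) / 2) / n_col[b]
  }, numeric(1))
  g1 <- c(0, cumsum(t1)); g2 <- c(0, cumsum(t2))
  FF <- FF - outer(g1, rep(1, K2 + 1L)) - outer(rep(1, K1 + 1L), g2)
  # center to data-weighted mean zero
  cell_avg <- (FF[-(K1 + 1L), -(K2 + 1L)] + FF[-1L, -(K2 + 1L)] +
               FF[-(K1 + 1L), -1L] + FF[-1L, -1L]) / 4
  FF <- FF - sum(n_cell * cell_avg) / sum(n_cell)
  list(x_i = ei, x_j = ej, ale = FF, filled = filled, n = n_cell)
}

#' Pairwise interaction strength (Friedman's H)
#'
#' For each feature pair, centered partial dependences are estimated on a
#' sampled grid (each sampled point's pair values against the sampled
#' background) and combined into Friedman's H statistic,
#' \deqn{H^2 = \sum_i [PD_{jk}(x_i) - PD_j(x_i) - PD_k(x_i)]^2 /
#'       \sum_i PD_{jk}(x_i)^2,}
#' reported as H in \[0, 1\] (numerical excursions above 1 are clipped and
#' flagged). H is 0 for additive pairs and 1 for a pure multiplicative
#' interaction of independent centered features, and is invariant to affine
#' rescaling of the response.
#'
#' @param model As in [ale_first_order()].
#' @param data Data.frame of feature values.
#' @param features Features to consider (default all columns of `data`);
#'   alternatively give `pairs` explicitly.
#' @param pairs Optional 2-column character matrix of pairs.
#' @param n_sample Sample size for the evaluation grid and background
#'   (default min(500, n)).
#' @param seed Integer seed for the sample.
#' @return Symmetric matrix of H values (diagonal NA) with attributes
#'   `n_sample` and `clipped`. Pairs with zero-variance joint partial
#'   dependence are NA.
#' @export
interaction_strength <- function(model, data, features = NULL, pairs = NULL,
                                 n_sample = NULL, seed = 1) {
  pf <- as_predict_fun(model)
  if (is.null(features)) features <- names(data)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(features, 2))
  }
  n_sample <- n_sample %||% min(500L, nrow(data))
  assert_that(n_sample <= nrow(data), "n_sample exceeds data size")
  S <- with_seed(seed, data[sample.int(nrow(data), n_sample), , drop = FALSE])
  n <- nrow(S)
  idx_bg <- rep(seq_len(n), times = n)   # background rows
  idx_pt <- rep(seq_len(n), each = n)    # evaluation points

  pd_cache <- new.env(parent = emptyenv())
  pd_one <- function(feats) {
    key <- paste(sort(feats), collapse = "|")
    if (!is.null(pd_cache[[key]])) return(pd_cache[[key]])
    nd <- S[idx_bg, , drop = FALSE]
    for (f in feats) nd[[f]] <- S[[f]][idx_pt]
    pred <- pf(nd)
    pd <- rowMeans(matrix(pred, nrow = n, byrow = TRUE))
    pd <- pd - mean(pd)
    pd_cache[[key]] <- pd
    pd
  }
  all_feats <- unique(as.vector(pairs))
  H <- matrix(NA_real_, length(all_feats), length(all_feats),
              dimnames = list(all_feats, all_feats))
  clipped <- FALSE
  for (r in seq_len(nrow(pairs))) {
    fj <- pairs[r, 1]; fk <- pairs[r, 2]
    pd_j <- pd_one(fj); pd_k <- pd_one(fk); pd_jk <- pd_one(c(fj, fk))
    denom <- sum(pd_jk^2)
    if (denom < .Machine$double.eps * n) {
      h <- NA_real_
    } else {
      h2 <- sum((pd_jk - pd_j - pd_k)^2) / denom
      if (h2 > 1) { h2 <- 1; clipped <- TRUE }
      h <- sqrt(h2)
    }
    H[fj, fk] <- H[fk, fj] <- h
  }
  attr(H, "n_sample") <- n
  attr(H, "clipped") <- clipped
  H
}
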