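make_bench <- function(n = 2000, seed = 10) {
  set.seed(seed)
  X <- data.frame(x1 = runif(n, -1, 1), x2 = runif(n, -1, 1),
                  x3 = runif(n, -1, 1), x4 = runif(n, -1, 1),
                  n1 = runif(n, -1, 1), n2 = runif(n, -1, 1))
  y <- 3 * X$x1 + 2 * X$x2 - 1.5 * X$x3 + 2 * X$x3 * X$x4
  list(X = X, y = y)
}

test_that("redundancy reduction groups correlated features transitively", {
  b <- make_bench(500)
  X <- b$X
  # duplicated feature: exactly one of the pair kept
  X$x1dup <- X$x1
  rr <- reduce_redundancy(X, b$y)
  expect_true(xor("x1" %in% rr$retained, "x1dup" %in% rr$retained))
  # mutually uncorrelated features all kept
  expect_true(all(c("x2", "x3", "x4", "n1", "n2") %in% rr$retained))
  # representatives pairwise below the cutoff
  cm <- abs(stats::cor(X[rr$retained]))
  expect_true(all(cm[upper.tri(cm)] < 0.8))
  # constructed triple: F1 = F2, F1 stronger on the response, F3 independent
  set.seed(4)
  F1 <- b$y + rnorm(500, sd = 0.5)
  tri <- data.frame(F1 = F1, F2 = F1, F3 = rnorm(500))
  rr2 <- reduce_redundancy(tri, b$y)
  expect_setequal(rr2$retained, c("F1", "F3"))
  # idempotent on its own output
  rr3 <- reduce_redundancy(X[rr$retained], b$y)
  expect_setequal(rr3$retained, rr$retained)
  # constant features removed first, with a report
  X$flat <- 1
  rr4 <- reduce_redundancy(X, b$y)
  expect_equal(rr4$dropped_constant, "flat")
  # transitive closure: chain A~B, B~C groups all three
  set.seed(6)
  A <- rnorm(500); B <- 0.95 * A + 0.31 * rnorm(500); C <- 0.95 * B + 0.31 * rnorm(500)
  chain <- data.frame(A = A, B = B, C = C)
  if (abs(cor(A, B)) >= 0.8 && abs(cor(B, C)) >= 0.8 && abs(cor(A, C)) < 0.8) {
    rrc <- reduce_redundancy(chain, b$y)
    expect_equal(length(rrc$retained), 1)
  }
})

test_that("grouped response scoring sums correlations over entities", {
  set.seed(8)
  by <- rep(c("p1", "p2"), each = 50)
  f_good <- c(seq_len(50), -seq_len(50)) + rnorm(100, sd = 2)
  y <- c(seq_len(50), -seq_len(50))
  X <- data.frame(good = f_good, dup = f_good + rnorm(100, sd = 0.1),
                  noise = rnorm(100))
  rr <- reduce_redundancy(X, y, by = by)
  # within each entity the good feature correlates strongly; it (or its
  # near-duplicate) represents the group
  expect_true(any(c("good", "dup") %in% rr$retained))
  expect_equal(length(rr$retained), 2)
})

test_that("the forest learns deterministic functions and not noise", {
  b <- make_bench()
  m <- fit_model(b$X, b$y, seed = 7)
  expect_gte(m$var_explained_test, 0.9)
  expect_gte(m$var_explained_oob, 0.9)
  # split is seeded and disjoint/exhaustive
  m2 <- fit_model(b$X, b$y, seed = 7)
  expect_identical(m$train_idx, m2$train_idx)
  expect_identical(sort(c(m$train_idx, m$test_idx)), seq_len(nrow(b$X)))
  expect_equal(length(m$train_idx) / nrow(b$X), 0.85, tolerance = 0.001)
  # pure-noise response explains nothing held out
  set.seed(70)
  ves <- vapply(1:5, function(s) {
    fit_model(b$X[1:500, ], rnorm(500), seed = s)$var_explained_test
  }, numeric(1))
  expect_lte(stats::median(ves), 0.1)
  expect_error(fit_model(b$X, rep(1, nrow(b$X))), "constant")
  expect_error(fit_model(b$X[1:20, ], b$y[1:20]), "at least 50")
})

test_that("drop-and-refit importance ranks generating features first", {
  b <- make_bench(1200)
  m <- fit_model(b$X, b$y, n_trees = 300, seed = 11)
  imp <- drop_importance(m)
  expect_setequal(imp$feature[1:4], c("x1", "x2", "x3", "x4"))
  expect_equal(imp$feature[which.max(imp$delta_mae)], "x1")
  # absent features gain nothing by inclusion; clipped at zero in the report
  expect_true(all(imp$delta_mae_clipped >= 0))
  expect_true(all(imp$delta_mae[imp$feature %in% c("n1", "n2")] < 0.1))
  expect_error(drop_importance(fit_model(b$X[, 1, drop = FALSE], b$y,
                                         n_trees = 50, seed = 1)),
               "at least 2")
  # permutation alternative ranks the strongest generating feature first too
  imp_p <- drop_importance(m, method = "permute")
  expect_equal(imp_p$feature[1], "x1")
  expect_true(all(imp_p$delta_mae[imp_p$feature %in% c("n1", "n2")] < 0.1))
})

test_that("first-order ALE recovers linear effects and ignores absent ones", {
  b <- make_bench(1500)
  f <- function(nd) 2 * nd$x1
  a <- ale_first_order(f, b$X, "x1")
  slope <- unname(stats::coef(stats::lm(ale ~ x, a))[2])
  expect_lt(abs(slope - 2) / 2, 0.1)
  # data-weighted mean of the profile is (approximately) zero
  n_bin <- attr(a, "n")
  mid <- (a$ale[-1] + a$ale[-nrow(a)]) / 2
  expect_lt(abs(sum(n_bin * mid) / sum(n_bin)), 1e-10)
  # feature the model never uses: identically zero
  a0 <- ale_first_order(f, b$X, "x2")
  expect_lt(max(abs(a0$ale)), 1e-10)
  # constant shifts leave ALE unchanged
  a_c <- ale_first_order(function(nd) 2 * nd$x1 + 100, b$X, "x1")
  expect_equal(a$ale, a_c$ale, tolerance = 1e-10)
  # constant feature: flat zero with warning
  Xc <- b$X; Xc$flat <- 1
  expect_warning(af <- ale_first_order(f, Xc, "flat"), "constant")
  expect_true(all(af$ale == 0))
  # fitted forest on a linear signal reproduces the slope within 10%
  m <- fit_model(b$X[, c("x1", "n1")], 2 * b$X$x1, n_trees = 300, seed = 3)
  a_rf <- ale_first_order(m, m$data, "x1", n_bins = 10)
  inner <- a_rf$x > -0.8 & a_rf$x < 0.8  # trees flatten at the extremes
  slope_rf <- unname(stats::coef(stats::lm(ale ~ x, a_rf[inner, ]))[2])
  expect_lt(abs(slope_rf - 2) / 2, 0.1)
})

test_that("second-order ALE isolates interactions", {
  b <- make_bench(2000)
  # additive oracle: second-order surface vanishes
  fa <- function(nd) sin(nd$x1) + nd$x2^2
  s_add <- ale_second_order(fa, b$X, "x1", "x2")
  expect_lt(max(abs(s_add$ale)), 0.05 * stats::sd(fa(b$X)))
  # multiplicative oracle: saddle with corner signs (+, -, -, +)
  fm <- function(nd) nd$x1 * nd$x2
  s <- ale_second_order(fm, b$X, "x1", "x2")
  K <- dim(s$ale)
  expect_gt(s$ale[1, 1], 0.5)
  expect_lt(s$ale[1, K[2]], -0.5)
  expect_lt(s$ale[K[1], 1], -0.5)
  expect_gt(s$ale[K[1], K[2]], 0.5)
  # close to the closed form x1 * x2 at the grid corners
  expect_lt(abs(s$ale[1, 1] - 1), 0.15)
  # symmetry under argument exchange
  s_t <- ale_second_order(fm, b$X, "x2", "x1")
  expect_lt(max(abs(s$ale - t(s_t$ale))), 1e-10)
})

test_that("ALE estimates tighten with more data and bins", {
  # the reference slope is exact for a linear model; a curved oracle's
  # binned estimate must approach it as n and the bin count grow
  f <- function(nd) nd$x1^3
  errs <- vapply(c(200, 5000), function(n) {
    set.seed(1)
    X <- data.frame(x1 = runif(n, -1, 1), x2 = runif(n, -1, 1))
    a <- ale_first_order(f, X, "x1", n_bins = if (n > 1000) 40 else 5)
    truth <- a$x^3 - mean(X$x1^3)
    max(abs(a$ale - truth))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("Friedman's H separates additive from interacting pairs", {
  b <- make_bench(1500)
  H_add <- interaction_strength(function(nd) nd$x1 + nd$x2, b$X,
                                features = c("x1", "x2"), n_sample = 300)
  expect_lt(H_add["x1", "x2"], 0.05)
  # pure product of independent centered features: H = 1
  fm <- function(nd) nd$x1 * nd$x2
  H_mul <- interaction_strength(fm, b$X, features = c("x1", "x2"),
                                n_sample = 300)
  expect_lt(abs(H_mul["x1", "x2"] - 1), 0.1)
  # affine response rescaling leaves H unchanged
  H_aff <- interaction_strength(function(nd) 5 * nd$x1 * nd$x2 - 3, b$X,
                                features = c("x1", "x2"), n_sample = 300)
  expect_equal(H_aff["x1", "x2"], H_mul["x1", "x2"], tolerance = 1e-8)
  # symmetric output with NA diagonal
  expect_true(is.na(H_mul["x1", "x1"]))
  expect_equal(H_mul["x1", "x2"], H_mul["x2", "x1"])
  # interacting pair dominates non-interacting pairs in a mixed model
  fmix <- function(nd) nd$x1 * nd$x2 + nd$x3
  H_mix <- interaction_strength(fmix, b$X, features = c("x1", "x2", "x3"),
                                n_sample = 250)
  expect_gt(H_mix["x1", "x2"], H_mix["x1", "x3"])
  expect_gt(H_mix["x1", "x2"], H_mix["x2", "x3"])
})
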