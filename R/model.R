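#' Correlation-based feature redundancy reduction
#'
#' Features are grouped by the transitive closure of the relation
#' |pairwise Pearson correlation| >= `cutoff`; within each group the
#' retained representative is the feature with the largest explanatory
#' score: the absolute correlation with the response, summed over the levels
#' of `by` when a grouping is supplied (e.g. summed across positions for
#' motif features, across motifs for recipient features). Constant features
#' are removed first and reported. Applying the reduction to its own output
#' changes nothing.
#'
#' @param features Data.frame or matrix of numeric features (rows =
#'   observations).
#' @param response Numeric response vector.
#' @param cutoff Absolute-correlation cutoff, default 0.8.
#' @param by Optional factor (length nrow) over whose levels response
#'   correlations are computed and summed.
#' @return `dip_featureset`: list with `retained`, `groups` (data.frame:
#'   feature, group, representative, score), `dropped_constant`.
#' @export
reduce_redundancy <- function(features, response, cutoff = 0.8, by = NULL) {
  x <- as.data.frame(features)
  num <- vapply(x, is.numeric, logical(1))
  x <- x[, num, drop = FALSE]
  assert_that(ncol(x) >= 2, "need at least 2 numeric features")
  assert_that(sum(stats::complete.cases(x, response)) >= 10,
              "need at least 10 complete cases")
  sds <- vapply(x, function(v) stats::sd(v, na.rm = TRUE), numeric(1))
  constant <- names(x)[!is.finite(sds) | sds == 0]
  x <- x[, setdiff(names(x), constant), drop = FALSE]
  p <- ncol(x)
  cm <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  cm[is.na(cm)] <- 0
  pairs <- which(abs(cm) >= cutoff & upper.tri(cm), arr.ind = TRUE)
  grp <- components_from_pairs(p, pairs)

  score_one <- function(v) {
    if (is.null(by)) {
      ok <- !is.na(v) & !is.na(response)
      if (sum(ok) < 3 || stats::sd(v[ok]) == 0) return(0)
      abs(stats::cor(v[ok], response[ok]))
    } else {
      sum(vapply(split(seq_along(v), by), function(idx) {
        ok <- !is.na(v[idx]) & !is.na(response[idx])
        if (sum(ok) < 3 || stats::sd(v[idx][ok]) == 0 ||
            stats::sd(response[idx][ok]) == 0) return(0)
        abs(stats::cor(v[idx][ok], response[idx][ok]))
      }, numeric(1)))
    }
  }
  scores <- vapply(x, score_one, numeric(1))
  groups <- data.frame(feature = names(x), group = grp, score = scores,
                       stringsAsFactors = FALSE)
  reps <- vapply(split(groups, groups$group), function(g)
    g$feature[which.max(g$score)], character(1))
  groups$representative <- reps[as.character(groups$group)]
  retained <- unname(reps[order(as.integer(names(reps)))])
  retained <- retained[match(intersect(names(x), retained), retained)]
  structure(list(retained = retained, groups = groups,
                 dropped_constant = constant, cutoff = cutoff),
            class = "dip_featureset")
}

#' Fit the donor/recipient compatibility regression forest
#'
#' Random regression forest (500 trees by default, mtry = p/3 rounded,
#' default tree controls) on a seeded 85/15 train/test split of the
#' complete-case rows; reports variance explained (1 - MSE / Var(response))
#' on the held-out set and out-of-bag, and held-out mean absolute error.
#'
#' @param features Data.frame of numeric features.
#' @param response Numeric response.
#' @param n_trees Number of trees (default 500).
#' @param split Training fraction (default 0.85).
#' @param mtry Variables tried per split; default `max(1, round(p/3))`.
#' @param seed Integer seed fixing the split and the forest.
#' @return `dip_rf`: list with `forest`, `features`, `train_idx`,
#'   `test_idx`, `var_explained_test`, `var_explained_oob`, `mae_test`.
#' @export
fit_model <- function(features, response, n_trees = 500, split = 0.85,
                      mtry = NULL, seed = 1) {
  x <- as.data.frame(features)
  ok <- stats::complete.cases(x, response)
  x <- x[ok, , drop = FALSE]
  y <- response[ok]
  assert_that(nrow(x) >= 50, "need at least 50 complete-case rows")
  assert_that(stats::sd(y) > 0, "response is constant")
  if (is.null(mtry)) mtry <- max(1L, round(ncol(x) / 3))
  with_seed(seed, {
    n <- nrow(x)
    train_idx <- sort(sample.int(n, floor(split * n)))
    test_idx <- setdiff(seq_len(n), train_idx)
    rf <- randomForest::randomForest(
      x = x[train_idx, , drop = FALSE], y = y[train_idx],
      ntree = n_trees, mtry = mtry, importance = FALSE)
    pred <- stats::predict(rf, x[test_idx, , drop = FALSE])
    mse <- mean((pred - y[test_idx])^2)
    ve_test <- 1 - mse / stats::var(y[test_idx])
    structure(list(forest = rf, features = names(x),
                   data = x, response = y,
                   train_idx = train_idx, test_idx = test_idx,
                   var_explained_test = ve_test,
                   var_explained_oob = utils::tail(rf$rsq, 1),
                   mae_test = mean(abs(pred - y[test_idx])),
                   n_trees = n_trees, split = split, mtry = mtry,
                   seed = seed),
              class = "dip_rf")
  })
}

#' @export
print.dip_rf <- function(x, ...) {
  cat(sprintf(
    "<dip_rf> %d trees, %d features, n = %d (train %d / test %d)\n",
    x$n_trees, length(x$features), nrow(x$data),
    length(x$train_idx), length(x$test_idx)))
  cat(sprintf("  variance explained: held-out %.3f, out-of-bag %.3f\n",
              x$var_explained_test, x$var_explained_oob))
  invisible(x)
}

#' Drop-and-refit feature importance
#'
#' For each feature, the forest is refit without it on the same seeded
#' train/test split and the increase in held-out mean absolute error over
#' the baseline model is reported. The ranked report clips negative
#' increases at zero; raw values are retained. `method = "permute"` gives
#' the cheaper permutation alternative for comparison: the feature's
#' held-out column is shuffled (no refit) and the mean error increase over
#' `n_repeats` shuffles reported.
#'
#' @param model A `dip_rf` baseline from [fit_model()].
#' @param method `"drop"` (default, drop-and-refit) or `"permute"`.
#' @param n_repeats Shuffles per feature for `method = "permute"`.
#' @return Data.frame (`feature`, `delta_mae`, `delta_mae_clipped`, `rank`)
#'   sorted by decreasing importance.
#' @export
drop_importance <- function(model, method = c("drop", "permute"),
                            n_repeats = 5) {
  method <- match.arg(method)
  stopifnot(inherits(model, "dip_rf"))
  assert_that(length(model$features) >= 2,
              "drop importance needs at least 2 features")
  x <- model$data; y <- model$response
  deltas <- if (method == "drop") {
    vapply(model$features, function(f) {
      xf <- x[, setdiff(names(x), f), drop = FALSE]
      rf <- with_seed(model$seed, randomForest::randomForest(
        x = xf[model$train_idx, , drop = FALSE], y = y[model$train_idx],
        ntree = model$n_trees, mtry = max(1L, round(ncol(xf) / 3))))
      pred <- stats::predict(rf, xf[model$test_idx, , drop = FALSE])
      mean(abs(pred - y[model$test_idx])) - model$mae_test
    }, numeric(1))
  } else {
    xt <- x[model$test_idx, , drop = FALSE]
    yt <- y[model$test_idx]
    vapply(model$features, function(f) {
      maes <- with_seed(model$seed, vapply(seq_len(n_repeats), function(r) {
        xp <- xt
        xp[[f]] <- sample(xp[[f]])
        mean(abs(stats::predict(model$forest, xp) - yt))
      }, numeric(1)))
      mean(maes) - model$mae_test
    }, numeric(1))
  }
  out <- data.frame(feature = model$features, delta_mae = deltas,
                    delta_mae_clipped = pmax(deltas, 0),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$delta_mae), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Resolve a model argument to a vectorised prediction function over a
# data.frame of feature columns.
as_predict_fun <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "dip_rf")) {
    forest <- model$forest
    return(function(newdata) as.numeric(stats::predict(forest, newdata)))
  }
  if (inherits(model, "randomForest")) {
    return(function(newdata) as.numeric(stats::predict(model, newdata)))
  }
  stopf("cannot derive a prediction function from class '%s'",
        paste(class(model), collapse = "/"))
}
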