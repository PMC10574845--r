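# Regression models for SBP/DBP estimation: [0,1] column normalization,
# XGBoost under GP Bayesian hyper-parameter search (7-fold search CV,
# 10-fold training CV), the Nadam MLP baseline, and prediction with
# schema checking.

#' Reference XGBoost search space
#'
#' The published search spaces: learning rate [0.01, 1], maximum tree depth
#' [2, 15] (SBP) or [2, 20] (DBP), subsample [0.1, 1], column subsample
#' [0.1, 1], L2 lambda [1e-10 (SBP) / 1e-9 (DBP), 200], L1 alpha
#' [1e-10, 200], and 50-5100 (SBP) / 50-6000 (DBP) estimators. The
#' `"desk"` profile caps depth at 8 and estimators at 300 so that searches
#' complete quickly at desk scale.
#'
#' @param target `"sbp"` or `"dbp"`.
#' @param profile `"paper"` or `"desk"`.
#' @return A [search_space()].
#' @export
xgb_search_space <- function(target = c("sbp", "dbp"),
                             profile = c("paper", "desk")) {
  target <- match.arg(target)
  profile <- match.arg(profile)
  max_depth <- if (profile == "desk") 8 else if (target == "sbp") 15 else 20
  n_est <- if (profile == "desk") 300 else if (target == "sbp") 5100 else 6000
  lambda_lo <- if (target == "sbp") 1e-10 else 1e-9
  search_space(list(
    learning_rate = list(lower = 0.01, upper = 1.0, log = TRUE),
    max_depth = list(lower = 2, upper = max_depth, integer = TRUE),
    subsample = c(0.1, 1.0),
    colsample_bytree = c(0.1, 1.0),
    lambda = list(lower = lambda_lo, upper = 200, log = TRUE),
    alpha = list(lower = 1e-10, upper = 200, log = TRUE),
    n_estimators = list(lower = 50, upper = n_est, log = TRUE, integer = TRUE)
  ))
}

#' Min-max normalize feature columns to [0, 1]
#'
#' @param table Feature table.
#' @param features Feature column names (default [feature_columns()]).
#' @return List with `table` (normalized copy) and `bounds` (data frame of
#'   per-feature min/max for reuse at predict time). Constant columns map
#'   to 0 with a warning.
#' @export
normalize_columns <- function(table, features = feature_columns(table)) {
  bounds <- data.frame(feature = features,
                       min = vapply(features, function(f) min(table[[f]]), 1),
                       max = vapply(features, function(f) max(table[[f]]), 1))
  if (any(bounds$min == bounds$max)) {
    warning("constant feature column(s) mapped to 0: ",
            paste(features[bounds$min == bounds$max], collapse = ", "))
  }
  list(table = apply_normalization(table, bounds), bounds = bounds)
}

#' Apply stored normalization bounds
#'
#' Maps each feature through its training-time min-max bounds and clips to
#' [0, 1], so predict-time values outside the training range saturate.
#'
#' @param table Feature table.
#' @param bounds Bounds data frame from [normalize_columns()].
#' @return Normalized copy of `table`.
#' @export
apply_normalization <- function(table, bounds) {
  for (i in seq_len(nrow(bounds))) {
    f <- bounds$feature[i]
    lo <- bounds$min[i]
    hi <- bounds$max[i]
    table[[f]] <- if (hi > lo) pmin(pmax((table[[f]] - lo) / (hi - lo), 0), 1)
                  else rep(0, nrow(table))
  }
  table
}

.xgb_params <- function(hp, seed = 1L) {
  list(eta = hp$learning_rate, max_depth = hp$max_depth,
       subsample = hp$subsample, colsample_bytree = hp$colsample_bytree,
       lambda = hp$lambda, alpha = hp$alpha,
       objective = "reg:squarederror", nthread = 1,
       seed = as.integer(seed) %% .Machine$integer.max)
}

.cv_folds <- function(n, k, seed) {
  .with_seed(seed, function() sample(rep(seq_len(k), length.out = n)))
}

.xgb_fit <- function(X, y, hp, seed = 1L) {
  xgboost::xgb.train(params = .xgb_params(hp, seed),
                     data = xgboost::xgb.DMatrix(X, label = y),
                     nrounds = hp$n_estimators, verbose = 0)
}

.xgb_pred <- function(fit, X) {
  as.numeric(predict(fit, xgboost::xgb.DMatrix(X)))
}

# mean k-fold CV RMSE of an XGBoost fit at hyper-parameters hp
.xgb_cv_rmse <- function(hp, X, y, folds, seed) {
  fold_id <- .cv_folds(length(y), folds, seed)
  rmse <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    fit <- .xgb_fit(X[tr, , drop = FALSE], y[tr], hp, seed + f)
    pred <- .xgb_pred(fit, X[!tr, , drop = FALSE])
    sqrt(mean((pred - y[!tr])^2))
  }, numeric(1))
  mean(rmse)
}

#' Bayesian hyper-parameter search for the XGBoost regressor
#'
#' Minimizes the mean 7-fold cross-validated RMSE over the search space
#' with a Gaussian-process surrogate and expected-improvement acquisition
#' ([gp_minimize()]).
#'
#' @param table Normalized feature table (selected features only).
#' @param target Target column name.
#' @param features Feature columns to use.
#' @param space A [search_space()]; default [xgb_search_space()] `"desk"`
#'   profile for the target.
#' @param n_trials Total objective evaluations (>= 10, default 50).
#' @param folds Search cross-validation folds (default 7).
#' @param seed Integer seed.
#' @return List with `best` hyper-parameters, `best_value` (CV RMSE,
#'   mmHg) and the search `trace`.
#' @export
bayes_search <- function(table, target = "sbp",
                         features = feature_columns(table), space = NULL,
                         n_trials = 50, folds = 7, seed = 1L) {
  if (is.null(space)) {
    space <- xgb_search_space(if (target == "dbp") "dbp" else "sbp", "desk")
  }
  X <- as.matrix(table[features])
  if (!all(is.finite(X))) stop("non-finite feature values")
  y <- table[[target]]
  gp_minimize(function(hp) .xgb_cv_rmse(hp, X, y, folds, seed),
              space, n_trials = n_trials, seed = seed)
}

#' Train the XGBoost blood-pressure regressor
#'
#' Cross-validates at the given hyper-parameters (default 10-fold),
#' reporting per-fold RMSE/MAE, then fits the final gradient-boosted
#' ensemble on all rows.
#'
#' @param table Feature table (raw scale; normalization is fitted here and
#'   stored with the model).
#' @param target Target column name.
#' @param hp Named list of hyper-parameters (`learning_rate`, `max_depth`,
#'   `subsample`, `colsample_bytree`, `lambda`, `alpha`, `n_estimators`).
#' @param features Feature columns to use.
#' @param folds Training cross-validation folds (default 10).
#' @param seed Integer seed.
#' @return Object of class `bp_model` with the fitted predictor, ordered
#'   feature names, stored normalization bounds and `cv_metrics`.
#' @export
train_xgboost <- function(table, target = "sbp", hp,
                          features = feature_columns(table), folds = 10,
                          seed = 1L) {
  norm <- normalize_columns(table, features)
  X <- as.matrix(norm$table[features])
  if (!all(is.finite(X))) stop("non-finite feature values")
  y <- table[[target]]
  fold_id <- .cv_folds(length(y), folds, seed)
  cv <- do.call(rbind, lapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    fit <- .xgb_fit(X[tr, , drop = FALSE], y[tr], hp, seed + f)
    pred <- .xgb_pred(fit, X[!tr, , drop = FALSE])
    data.frame(fold = f, rmse = sqrt(mean((pred - y[!tr])^2)),
               mae = mean(abs(pred - y[!tr])))
  }))
  fit <- .xgb_fit(X, y, hp, seed)
  structure(list(kind = "xgboost", fit = fit, features = features,
                 bounds = norm$bounds, target = target, hp = hp,
                 cv_metrics = cv),
            class = "bp_model")
}

#' Train the neural-network baseline
#'
#' Fits the all-ReLU feed-forward network of [nn_config()] with Nadam on
#' mean squared error. Inputs get the same stored [0,1] normalization as
#' the gradient-boosted models.
#'
#' @param table Feature table.
#' @param target Target column name.
#' @param config An [nn_config()]; its input size is taken from
#'   `features`.
#' @param features Feature columns to use.
#' @param seed Integer seed.
#' @return `bp_model` with `history` (per-epoch training/validation loss)
#'   and `n_validation`.
#' @export
train_nn <- function(table, target = "sbp", config = nn_config(scale = "small"),
                     features = feature_columns(table), seed = 1L) {
  stopifnot(inherits(config, "nn_config"))
  norm <- normalize_columns(table, features)
  X <- as.matrix(norm$table[features])
  if (!all(is.finite(X))) stop("non-finite feature values")
  y <- table[[target]]
  fit <- .nn_train(X, y, config, seed)
  structure(list(kind = "nn", fit = fit$net, features = features,
                 bounds = norm$bounds, target = target, config = config,
                 history = fit$history, n_validation = fit$n_validation),
            class = "bp_model")
}

#' Predict blood pressure for new feature rows
#'
#' Features are matched by name (column order is irrelevant), checked for
#' completeness and finiteness, passed through the stored normalization
#' bounds (with clipping) and then through the fitted predictor.
#'
#' @param object A `bp_model`.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of predictions in mmHg.
#' @export
predict.bp_model <- function(object, newdata, ...) {
  missing_f <- setdiff(object$features, names(newdata))
  if (length(missing_f) > 0) {
    stop("missing feature column(s): ", paste(missing_f, collapse = ", "))
  }
  for (f in object$features) {
    bad <- !is.finite(newdata[[f]])
    if (any(bad)) {
      stop("non-finite value in feature '", f, "' (row ", which(bad)[1], ")")
    }
  }
  nd <- apply_normalization(newdata[object$features], object$bounds)
  X <- as.matrix(nd[object$features])
  if (object$kind == "xgboost") .xgb_pred(object$fit, X)
  else .nn_predict(object$fit, X)
}

#' @export
print.bp_model <- function(x, ...) {
  cat(sprintf("bp_model (%s) for %s: %d features\n", x$kind, x$target,
              length(x$features)))
  if (!is.null(x$cv_metrics)) {
    cat(sprintf("  CV RMSE %.3f mmHg, MAE %.3f mmHg (%d folds)\n",
                mean(x$cv_metrics$rmse), mean(x$cv_metrics$mae),
                nrow(x$cv_metrics)))
  }
  invisible(x)
}

#' Parameter-recovery benchmark of the full model path
#'
#' Generates a synthetic labeled feature set with a known generating model
#' (`SBP = g(features) + N(0, sigma)`, [simulate_bp_features()]), runs
#' mRMR selection, the GP hyper-parameter search and cross-validated
#' XGBoost training on a training split, and reports the RMSE on a
#' held-out test split. With enough rows the test RMSE approaches the
#' noise floor `sigma` from above.
#'
#' @param n_rows Total rows (default 50000).
#' @param sigma Target noise SD in mmHg (default 3).
#' @param target Target column.
#' @param n_trials Bayesian-search trials (default 20).
#' @param search_folds Search CV folds (default 5).
#' @param train_folds Final-fit CV folds (default 5).
#' @param test_fraction Held-out fraction (default 0.2).
#' @param seed Integer seed.
#' @return List with `metrics` (test-set [regression_metrics()]), `model`,
#'   `search`, and the row counts used.
#' @export
bp_recovery_benchmark <- function(n_rows = 50000, sigma = 3, target = "sbp",
                                  n_trials = 20, search_folds = 5,
                                  train_folds = 5, test_fraction = 0.2,
                                  seed = 1L) {
  tab <- simulate_bp_features(n_rows, sigma = sigma, seed = seed)
  n_test <- round(test_fraction * n_rows)
  idx_test <- seq_len(n_test) + (n_rows - n_test)
  train <- tab[-idx_test, ]
  test <- tab[idx_test, ]

  rank <- mrmr_rank(train, target, k = min(10, length(feature_columns(train))))
  feats <- rank$features
  # search on a capped subsample: the surrogate needs relative, not
  # absolute, objective values
  search_rows <- .with_seed(seed, function() {
    sample.int(nrow(train), min(nrow(train), 8000L))
  })
  search <- bayes_search(train[search_rows, ], target, features = feats,
                         space = xgb_search_space(target, "desk"),
                         n_trials = n_trials, folds = search_folds,
                         seed = seed)
  model <- train_xgboost(train, target, hp = search$best, features = feats,
                         folds = train_folds, seed = seed)
  pred <- predict(model, test)
  list(metrics = regression_metrics(pred, test[[target]]), model = model,
       search = search, n_train = nrow(train), n_test = nrow(test),
       selected = feats)
}
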