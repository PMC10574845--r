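test_that("min-max normalization and its reuse behave as declared", {
  tab <- data.frame(fa = c(2, 4, 6), fb = c(1, 1, 1),
                    sbp = c(100, 110, 120), dbp = c(70, 75, 80))
  expect_warning(norm <- normalize_columns(tab), "constant")
  expect_equal(norm$table$fa, c(0, 0.5, 1))
  expect_equal(norm$table$fb, c(0, 0, 0))
  # idempotent reuse of stored bounds
  again <- apply_normalization(tab, norm$bounds)
  expect_equal(again$fa, norm$table$fa)
  # predict-time clipping
  new <- apply_normalization(data.frame(fa = c(0, 8), fb = c(5, 5)),
                             norm$bounds)
  expect_equal(new$fa, c(0, 1))
})

test_that("search spaces reject inverted bounds and stay feasible", {
  expect_error(search_space(list(a = c(2, 1))), "inverted")
  sp <- xgb_search_space("sbp", "desk")
  set.seed(1)
  obj_hist <- list()
  res <- gp_minimize(function(hp) {
    obj_hist[[length(obj_hist) + 1]] <<- hp
    (hp$learning_rate - 0.2)^2
  }, sp, n_trials = 12, seed = 3)
  for (hp in obj_hist) {
    expect_gte(hp$learning_rate, 0.01); expect_lte(hp$learning_rate, 1)
    expect_gte(hp$max_depth, 2); expect_lte(hp$max_depth, 8)
    expect_gte(hp$n_estimators, 50); expect_lte(hp$n_estimators, 300)
    expect_true(is.integer(hp$max_depth))
  }
})

test_that("the GP search localizes a 1-D optimum and improves with budget", {
  sp <- search_space(list(lr = c(0.01, 1)))
  toy <- function(hp) 1 + 10 * (hp$lr - 0.1)^2
  hits <- 0
  best10 <- numeric(20)
  best40 <- numeric(20)
  for (s in 1:20) {
    r30 <- gp_minimize(toy, sp, n_trials = 30, seed = s)
    if (r30$best$lr >= 0.05 && r30$best$lr <= 0.2) hits <- hits + 1
    best10[s] <- gp_minimize(toy, sp, n_trials = 10, seed = s)$best_value
    best40[s] <- r30$best_value
  }
  expect_gte(hits, 18)
  expect_lte(mean(best40), mean(best10))
})

test_that("the search is reproducible under a fixed seed", {
  sp <- search_space(list(lr = c(0.01, 1), depth = list(lower = 2, upper = 8,
                                                        integer = TRUE)))
  toy <- function(hp) (hp$lr - 0.3)^2 + 0.01 * hp$depth
  r1 <- gp_minimize(toy, sp, n_trials = 15, seed = 9)
  r2 <- gp_minimize(toy, sp, n_trials = 15, seed = 9)
  expect_identical(r1$trace, r2$trace)
})

test_that("gradient boosting recovers a noiseless linear map", {
  set.seed(4)
  n <- 20000
  tab <- data.frame(f1 = runif(n), f2 = runif(n), f3 = runif(n))
  tab$sbp <- 100 + 30 * tab$f1 + 20 * tab$f2 - 10 * tab$f3
  tab$dbp <- runif(n, 60, 110)
  hp <- list(learning_rate = 0.3, max_depth = 6, subsample = 1,
             colsample_bytree = 1, lambda = 1, alpha = 1e-10,
             n_estimators = 300)
  m <- train_xgboost(tab, "sbp", hp, features = c("f1", "f2", "f3"),
                     folds = 5, seed = 1)
  expect_lt(mean(m$cv_metrics$rmse), 0.5)
  pred <- predict(m, tab)
  expect_lt(sqrt(mean((pred - tab$sbp)^2)), 0.5)
})

test_that("a constant target is fitted to a constant", {
  set.seed(5)
  tab <- data.frame(f1 = runif(500), f2 = runif(500))
  tab$sbp <- rep(123, 500)
  tab$dbp <- runif(500, 60, 110)
  hp <- list(learning_rate = 0.3, max_depth = 3, subsample = 1,
             colsample_bytree = 1, lambda = 1, alpha = 1e-10,
             n_estimators = 50)
  m <- train_xgboost(tab, "sbp", hp, features = c("f1", "f2"), folds = 3)
  expect_lt(mean(m$cv_metrics$rmse), 0.2)
  expect_equal(mean(predict(m, tab)), 123, tolerance = 0.2)
})

test_that("test error approaches the label noise floor", {
  hp <- list(learning_rate = 0.1, max_depth = 5, subsample = 0.9,
             colsample_bytree = 0.9, lambda = 1, alpha = 1e-10,
             n_estimators = 200)
  for (sigma in c(2, 5)) {
    train <- simulate_bp_features(15000, sigma = sigma, seed = 10)
    test <- simulate_bp_features(4000, sigma = sigma, seed = 11)
    m <- train_xgboost(train, "sbp", hp,
                       features = c("f1", "f2", "f3", "f4"), folds = 3)
    rmse <- sqrt(mean((predict(m, test) - test$sbp)^2))
    expect_gte(rmse, sigma * 0.97)
    expect_lte(rmse, sigma * 1.3)
  }
})

test_that("the all-ReLU network predicts non-negative pressures", {
  train <- simulate_bp_features(4000, sigma = 3, seed = 2)
  nn <- train_nn(train, "sbp", nn_config(scale = "small"), seed = 1)
  expect_true(all(predict(nn, train) >= 0))
  expect_equal(nn$n_validation, round(0.2 * nrow(train)))
  expect_identical(nrow(nn$history), 20L)
})

test_that("the scaled network stays within twice the boosted error", {
  train <- simulate_bp_features(6000, sigma = 3, seed = 12)
  test <- simulate_bp_features(2000, sigma = 3, seed = 13)
  feats <- c("f1", "f2", "f3", "f4")
  hp <- list(learning_rate = 0.1, max_depth = 5, subsample = 0.9,
             colsample_bytree = 0.9, lambda = 1, alpha = 1e-10,
             n_estimators = 200)
  xgb <- train_xgboost(train, "sbp", hp, features = feats, folds = 3)
  nn <- train_nn(train, "sbp", nn_config(scale = "small"), features = feats,
                 seed = 1)
  rmse <- function(m) sqrt(mean((predict(m, test) - test$sbp)^2))
  expect_lte(rmse(nn), 2 * rmse(xgb))
})

test_that("prediction is schema-checked and order-invariant", {
  train <- simulate_bp_features(1000, sigma = 3, seed = 3)
  hp <- list(learning_rate = 0.2, max_depth = 4, subsample = 1,
             colsample_bytree = 1, lambda = 1, alpha = 1e-10,
             n_estimators = 60)
  m <- train_xgboost(train, "sbp", hp, features = c("f1", "f2", "f3"),
                     folds = 3)
  nd <- train[, c("f3", "f1", "f2")]
  expect_equal(predict(m, nd), predict(m, train), tolerance = 1e-12)
  expect_error(predict(m, train[, c("f1", "f2")]), "missing feature")
  bad <- train
  bad$f2[5] <- NA
  expect_error(predict(m, bad), "f2")
})
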