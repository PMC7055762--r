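test_that("a stump's split matches exhaustive enumeration, with missing values", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 20L
    X <- matrix(rnorm(n * 3), n, 3)
    X[sample(length(X), 8)] <- NA
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    fit <- fit_gbm(X, y, control = gbm_control(max_depth = 1,
                                               max_trees = 1,
                                               min_child_weight = 0,
                                               learning_rate = 1))
    tree <- fit$trees[[1]]
    g <- rep(0.5, n) - y
    h <- rep(0.25, n)
    ora <- oracle_stump(X, g, h, min_child_weight = 0, lambda = 1)
    if (is.na(ora$feature)) {
      expect_identical(tree$feature[1], 0L)
    } else {
      expect_identical(tree$feature[1], ora$feature)
      expect_identical(tree$presence[1], ora$presence)
      if (!ora$presence) {
        expect_equal(tree$threshold[1], ora$threshold)
        expect_identical(tree$missing_left[1], ora$missing_left)
      }
    }
  }
})

test_that("boosting converges to the class rate on an uninformative feature", {
  set.seed(1)
  n <- 200L
  X <- matrix(1, n, 1)
  y <- rep(c(1, 0, 0, 0), n / 4)
  fit <- fit_gbm(X, y, control = gbm_control(max_trees = 200,
                                             learning_rate = 0.3))
  p <- predict(fit, X)
  expect_equal(unname(p), rep(0.25, n), tolerance = 1e-4)
})

test_that("a perfectly separating feature reaches training AUROC 1 after one tree", {
  X <- matrix(c(rep(0, 10), rep(1, 10)), ncol = 1)
  y <- c(rep(0, 10), rep(1, 10))
  fit <- fit_gbm(X, y, control = gbm_control(max_depth = 1, max_trees = 1))
  expect_equal(auroc(predict(fit, X), y), 1.0)
})

test_that("adding trees never increases training log-loss", {
  set.seed(99)
  n <- 150L
  X <- matrix(rnorm(n * 4), n, 4)
  X[sample(length(X), 60)] <- NA
  y <- rbinom(n, 1, plogis(ifelse(is.na(X[, 1]), 0, X[, 1])))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  ctl <- gbm_control(max_trees = 40, learning_rate = 0.3)
  fit <- fit_gbm(X, y, control = ctl)
  margin <- rep(0, n)
  ll_prev <- Inf
  for (tree in fit$trees) {
    margin <- margin + ctl$learning_rate *
      landboost:::lb_predict_tree(tree, X)
    p <- plogis(margin)
    ll <- -mean(y * log(p) + (1 - y) * log(1 - p))
    expect_lte(ll, ll_prev + 1e-12)
    ll_prev <- ll
  }
})

test_that("an empty ensemble and a single leaf obey the margin identities", {
  X <- matrix(0, 4, 1)
  fit0 <- fit_gbm(X, c(0, 1, 0, 1), base_margin = 0.7,
                  control = gbm_control(max_trees = 0))
  expect_equal(unname(predict(fit0, X, base_margin = 0.7)),
               rep(plogis(0.7), 4))
  expect_equal(unname(predict(fit0, X, base_margin = 0.7, type = "link")),
               rep(0.7, 4))
  # constant feature -> every tree is a single leaf; after one tree the
  # probability is sigmoid(learning_rate * leaf weight)
  y <- c(1, 1, 1, 0)
  fit1 <- fit_gbm(X, y, control = gbm_control(max_trees = 1,
                                              learning_rate = 0.1))
  w <- fit1$trees[[1]]$value[1]
  expect_equal(unname(predict(fit1, X))[1], plogis(0.1 * w))
})

test_that("missing rows follow the stored missing-direction at prediction", {
  # force a split on a feature, then predict a row that is missing it
  set.seed(3)
  x <- c(rnorm(10, -2), rnorm(10, 2))
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "f"))
  y <- rep(c(0, 1), each = 10)
  fit <- fit_gbm(X, y, control = gbm_control(max_depth = 1, max_trees = 1))
  tree <- fit$trees[[1]]
  expect_identical(tree$feature[1], 1L)
  Xna <- matrix(NA_real_, 1, 1, dimnames = list(NULL, "f"))
  p <- predict(fit, Xna, type = "link")
  side <- if (tree$missing_left[1]) tree$left[1] else tree$right[1]
  expect_equal(unname(p), fit$learning_rate * tree$value[side])
  # a column absent from the prediction matrix is treated as missing
  Xother <- matrix(0, 1, 1, dimnames = list(NULL, "other"))
  expect_equal(predict(fit, Xother, type = "link"), p)
})

test_that("fits are invariant to row order and reproducible", {
  # tie-free data: split choices are unambiguous, so reordering the rows
  # can only move floating-point sums by rounding error
  set.seed(8)
  n <- 60L
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.numeric(X[, 1] + 0.2 * X[, 2] > 0)
  ctl <- gbm_control(max_trees = 5, max_depth = 2)
  fit1 <- fit_gbm(X, y, control = ctl)
  fit2 <- fit_gbm(X, y, control = ctl)
  expect_identical(predict(fit1, X), predict(fit2, X))
  perm <- sample(n)
  fit3 <- fit_gbm(X[perm, ], y[perm], control = ctl)
  expect_equal(unname(predict(fit3, X)), unname(predict(fit1, X)),
               tolerance = 1e-9)
})

test_that("single-class targets give a warned degenerate constant fit", {
  X <- matrix(rnorm(10), ncol = 1)
  expect_warning(fit <- fit_gbm(X, rep(1, 10)), "single-class")
  expect_length(fit$trees, 0)
  expect_true(all(predict(fit, X) > 0.99))
})

test_that("model serialisation round-trips bit-exactly", {
  set.seed(5)
  X <- matrix(rnorm(200), 50, 4)
  X[sample(length(X), 40)] <- NA
  y <- rbinom(50, 1, 0.4)
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  fit <- fit_gbm(X, y, control = gbm_control(max_trees = 12))
  path <- tempfile(fileext = ".json")
  gbm_save(fit, path)
  back <- gbm_load(path)
  expect_identical(back$trees, fit$trees)
  expect_identical(back$learning_rate, fit$learning_rate)
  expect_identical(predict(back, X), predict(fit, X))
})

test_that("cross-validation tuning honours its tie and argmax contracts", {
  set.seed(21)
  n <- 120L
  X <- matrix(rnorm(n * 2), n, 2)
  y <- rbinom(n, 1, plogis(X[, 1]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  ctl <- gbm_control(max_trees = 10)
  one <- tune_by_cv(X, y, grid = data.frame(max_depth = 4), control = ctl,
                    folds = 5, seed = 1)
  expect_identical(one$best$max_depth, 4L)
  # two identical rows: the first wins by the tie rule
  two <- tune_by_cv(X, y, grid = data.frame(max_depth = c(3, 3),
                                            learning_rate = c(0.1, 0.1)),
                    control = ctl, folds = 5, seed = 1)
  expect_identical(two$scores$mean_auc[1], two$scores$mean_auc[2])
  expect_identical(two$best$max_depth, 3L)
  # fewer rows than folds reduces the fold count with a warning
  expect_warning(
    tune_by_cv(X[1:6, ], y[1:6] * 0 + c(0, 1), grid =
                 data.frame(max_depth = 2), control = ctl, folds = 10,
               seed = 1),
    "reducing folds")
})

test_that("cross-validation prefers deeper trees when the signal is an interaction", {
  wins <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    n <- 300L
    X <- matrix(rnorm(n * 2), n, 2)
    y <- rbinom(n, 1, plogis(2.2 * sign(X[, 1] * X[, 2])))
    res <- tune_by_cv(X, y, grid = data.frame(max_depth = c(1, 3)),
                      control = gbm_control(max_trees = 30,
                                            learning_rate = 0.3),
                      folds = 10, seed = seed)
    if (res$best$max_depth >= 2) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("predictions agree with an established boosting library on dense data", {
  skip_if_not_installed("xgboost")
  set.seed(17)
  n <- 400L
  X <- matrix(rnorm(n * 5), n, 5)
  y <- rbinom(n, 1, plogis(0.8 * X[, 1] - 0.6 * X[, 3]))
  ctl <- gbm_control(max_depth = 3, learning_rate = 0.1,
                     min_child_weight = 1, max_trees = 60, lambda = 1)
  ours <- fit_gbm(X, y, control = ctl)
  xgb <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 3, eta = 0.1,
                  min_child_weight = 1, lambda = 1, base_score = 0.5,
                  tree_method = "exact", nthread = 1),
    data = xgboost::xgb.DMatrix(X, label = y), nrounds = 60)
  p1 <- predict(ours, X)
  p2 <- predict(xgb, xgboost::xgb.DMatrix(X))
  expect_lt(mean(abs(p1 - p2)), 0.05)
})
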