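test_that("pcc matches the covariance formula and handles edge cases", {
  x <- c(1, 2, 3)
  y <- c(2, 4, 5)
  # direct evaluation of the product-moment formula
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pcc(x, y), num / den)
  expect_equal(pcc(x, x), 1)
  expect_equal(pcc(x, -x), -1)
  expect_error(pcc(x, c(1, 1, 1)), "constant")
  expect_error(pcc(x, y[1:2]), "lengths differ")
  expect_error(pcc(x[1:2], y[1:2]), "at least 3")
})

test_that("pcc is invariant under positive affine maps, sign-flips under negative", {
  withr::with_seed(41, {
    x <- rnorm(50)
    y <- x + rnorm(50)
  })
  r <- pcc(x, y)
  expect_equal(pcc(3 + 2 * x, y), r)
  expect_equal(pcc(x, -0.5 * y + 1), -r)
})

test_that("cross-validated PCC recovers learnable limits and nulls", {
  withr::with_seed(42, {
    x <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
    y_lin <- 2 * x[, "a"] + 1
    y_noise <- rnorm(200)
  })
  cv_lin <- cv_pcc(learner_elasticnet(), x, y_lin, seed = 1)
  expect_gte(cv_lin$mean_pcc, 0.99)
  cv_tree <- cv_pcc(learner_xgboost(), x, y_lin, seed = 1)
  expect_gte(cv_tree$mean_pcc, 0.95)
  cv_null <- cv_pcc(learner_xgboost(), x, y_noise, seed = 1)
  expect_lt(abs(cv_null$mean_pcc), 0.2)
})

test_that("folds and CV results are deterministic in the seed", {
  withr::with_seed(43, {
    x <- matrix(rnorm(100 * 4), 100, 4, dimnames = list(NULL, paste0("f", 1:4)))
    y <- x[, 1] + rnorm(100, 0, 0.5)
  })
  a <- cv_pcc(learner_xgboost(nrounds = 50), x, y, seed = 9)
  b <- cv_pcc(learner_xgboost(nrounds = 50), x, y, seed = 9)
  expect_identical(a$mean_pcc, b$mean_pcc)
  expect_identical(a$folds, b$folds)
  expect_equal(sort(unique(a$folds)), 1:10)
  expect_true(max(table(a$folds)) - min(table(a$folds)) <= 1)
})

test_that("a one-row grid reduces tuning to a direct fit", {
  withr::with_seed(44, {
    x <- matrix(rnorm(120 * 5), 120, 5, dimnames = list(NULL, paste0("f", 1:5)))
    y <- x[, 1] - x[, 2] + rnorm(120, 0, 0.5)
  })
  grid <- tibble::tibble(max_depth = 3, eta = 0.1, nrounds = 80)
  m <- tune_and_train(x, y, grid = grid, seed = 2)
  direct <- fit_learner(learner_xgboost(max_depth = 3, eta = 0.1, nrounds = 80),
                        x, y, seed = 2)
  expect_equal(predict(m, x), predict_learner(direct, x))
  expect_equal(m$params$max_depth, 3)
})

test_that("held-out PCC reaches the oracle ceiling on a planted design", {
  d <- planted_design(n = 700, p = 20, k = 4, r2 = 0.45, seed = 3,
                      signal = "step")
  train <- 1:400
  test <- 401:700
  m <- tune_and_train(d$x[train, ], d$y[train], seed = 3)
  held <- pcc(d$y[test], predict(m, d$x[test, ]))
  expect_lt(abs(held - d$ceiling), 0.1)
})

test_that("a saved model reloads with identical predictions", {
  withr::with_seed(45, {
    x <- matrix(rnorm(80 * 4), 80, 4, dimnames = list(NULL, paste0("f", 1:4)))
    y <- x[, 1] + rnorm(80, 0, 0.3)
  })
  for (kind in c("xgboost", "elasticnet", "adaboost")) {
    grid <- switch(kind, xgboost = tibble::tibble(max_depth = 2, nrounds = 40),
                   elasticnet = tibble::tibble(alpha = 0.5),
                   adaboost = tibble::tibble(n_rounds = 10, max_depth = 2))
    m <- tune_and_train(x, y, kind = kind, grid = grid, k = 5, seed = 4)
    path <- withr::local_tempfile(fileext = ".rds")
    save_dose_model(m, path)
    m2 <- load_dose_model(path)
    expect_identical(predict(m2, x), predict(m, x))
  }
})

test_that("models refuse prediction without their training columns", {
  withr::with_seed(46, {
    x <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, c("a", "b", "dose")))
    y <- x[, 1] + rnorm(60, 0, 0.3)
  })
  m <- tune_and_train(x, y, grid = tibble::tibble(max_depth = 2, nrounds = 30),
                      k = 5, seed = 1)
  expect_error(predict(m, x[, c("a", "b")]), "lacks columns")
})

test_that("algorithm comparison shares folds and ranks by structure", {
  # strongly nonlinear response: threshold interactions favour trees
  withr::with_seed(47, {
    n <- 250
    x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
    y_nl <- 2 * (x[, 1] > 0) * (x[, 2] > 0) - 1.5 * (x[, 3] > 0.5) +
      rnorm(n, 0, 0.5)
  })
  cmp <- compare_algorithms(x, y_nl, k = 5, seed = 2,
                            learners = list(
                              xgboost = learner_xgboost(nrounds = 150),
                              adaboost = learner_adaboost(n_rounds = 20),
                              elasticnet = learner_elasticnet()))
  pc <- setNames(cmp$cv_pcc, cmp$algorithm)
  expect_gt(pc[["xgboost"]], pc[["elasticnet"]])
  expect_gt(pc[["adaboost"]], pc[["elasticnet"]])
  expect_length(attr(cmp, "folds"), nrow(x))

  # purely linear response at large n: the elastic net is competitive
  withr::with_seed(48, {
    n <- 400
    xl <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
    y_lin <- as.numeric(xl %*% c(1, -0.8, 0.6, rep(0, 7))) + rnorm(n, 0, 1)
  })
  cmp2 <- compare_algorithms(xl, y_lin, k = 5, seed = 2,
                             learners = list(
                               xgboost = learner_xgboost(nrounds = 150),
                               elasticnet = learner_elasticnet()))
  pc2 <- setNames(cmp2$cv_pcc, cmp2$algorithm)
  expect_gte(pc2[["elasticnet"]], pc2[["xgboost"]] - 0.05)
})

test_that("repeated tuning shows no systematic CV optimism over held-out", {
  gaps <- vapply(1:6, function(s) {
    d <- planted_design(n = 300, p = 15, k = 3, r2 = 0.45, seed = 100 + s,
                        signal = "step")
    train <- 1:200
    test <- 201:300
    m <- tune_and_train(d$x[train, ], d$y[train],
                        grid = tibble::tibble(max_depth = c(2, 3), nrounds = 200),
                        seed = s)
    m$cv_pcc - pcc(d$y[test], predict(m, d$x[test, ]))
  }, numeric(1))
  expect_lte(mean(gaps), 0.05) # "no obvious overfitting"
})
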