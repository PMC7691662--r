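#' Learner specifications
#'
#' Lightweight specs for the three regression algorithm families compared in
#' the pipeline: gradient-boosted trees (xgboost), adaptive boosting of
#' shallow regression trees (AdaBoost.R2 over rpart weak learners), and
#' elastic-net-penalised linear regression (glmnet, penalty chosen by internal
#' cross-validation). A spec is fit with `fit_learner()` and scored with
#' `predict_learner()`; both are deterministic given the seed.
#'
#' @param max_depth,eta,nrounds,min_child_weight,subsample,tree_method,max_bin
#'   Usual xgboost regression parameters.
#' @return A list of class `learner_spec`.
#' @export
learner_xgboost <- function(max_depth = 2, eta = 0.05, nrounds = 300,
                            min_child_weight = 5, subsample = 1,
                            gamma = 0,
                            tree_method = "hist", max_bin = 16) {
  structure(list(kind = "xgboost",
                 params = list(max_depth = max_depth, eta = eta,
                               gamma = gamma,
                               min_child_weight = min_child_weight,
                               subsample = subsample, tree_method = tree_method,
                               max_bin = max_bin),
                 nrounds = nrounds),
            class = "learner_spec")
}

#' @rdname learner_xgboost
#' @param n_rounds Number of boosting rounds (weak learners).
#' @param loss Loss function for AdaBoost.R2: `"linear"`, `"square"` or
#'   `"exponential"`.
#' @export
learner_adaboost <- function(n_rounds = 50, max_depth = 3,
                             loss = c("linear", "square", "exponential")) {
  structure(list(kind = "adaboost",
                 params = list(n_rounds = n_rounds, max_depth = max_depth,
                               loss = match.arg(loss))),
            class = "learner_spec")
}

#' @rdname learner_xgboost
#' @param alpha Elastic-net mixing parameter (1 = lasso, 0 = ridge).
#' @param nfolds Internal folds for the penalty search.
#' @export
learner_elasticnet <- function(alpha = 0.5, nfolds = 5) {
  structure(list(kind = "elasticnet",
                 params = list(alpha = alpha, nfolds = nfolds)),
            class = "learner_spec")
}

#' @rdname learner_xgboost
#' @export
learner_stump <- function() {
  structure(list(kind = "stump", params = list()), class = "learner_spec")
}

#' Fit / predict a learner spec
#'
#' @param spec A `learner_spec`.
#' @param x Numeric feature matrix with column names.
#' @param y Numeric response.
#' @param seed Integer seed (xgboost and glmnet internals).
#' @return `fit_learner()` returns a `fitted_learner`; `predict_learner()` a
#'   numeric vector of predictions.
#' @export
fit_learner <- function(spec, x, y, seed = 1L) {
  assert_that(inherits(spec, "learner_spec"), "spec must be a learner_spec")
  assert_that(nrow(x) == length(y), "x and y are misaligned")
  fit <- switch(spec$kind,
    xgboost = {
      dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
      params <- c(spec$params,
                  list(nthread = 1, objective = "reg:squarederror",
                       seed = derive_seed(seed, 7L)))
      xgboost::xgb.train(params = params, data = dm,
                         nrounds = spec$nrounds, verbose = 0)
    },
    adaboost = fit_adaboost_r2(x, y, spec$params),
    elasticnet = withr::with_seed(derive_seed(seed, 13L), {
      glmnet::cv.glmnet(x, y, alpha = spec$params$alpha,
                        nfolds = spec$params$nfolds)
    }),
    stump = fit_stump(x, y)
  )
  structure(list(kind = spec$kind, spec = spec, fit = fit,
                 features = colnames(x)),
            class = "fitted_learner")
}

#' @rdname fit_learner
#' @param object A `fitted_learner`.
#' @param newx Matrix with (at least) the training columns.
#' @export
predict_learner <- function(object, newx) {
  assert_that(inherits(object, "fitted_learner"), "object must be a fitted_learner")
  missing <- setdiff(object$features, colnames(newx))
  assert_that(length(missing) == 0,
              paste("prediction matrix lacks columns:",
                    paste(utils::head(missing, 5), collapse = ", ")))
  newx <- newx[, object$features, drop = FALSE]
  switch(object$kind,
    xgboost = predict(object$fit, xgboost::xgb.DMatrix(newx, nthread = 1)),
    adaboost = predict_adaboost_r2(object$fit, newx),
    elasticnet = as.numeric(predict(object$fit, newx, s = "lambda.min")),
    stump = predict_stump(object$fit, newx)
  )
}

# names of features used in at least one split (importance > 0); parsed from
# the tree dump, which is reliable for any booster size
used_features <- function(fitted) {
  switch(fitted$kind,
    xgboost = {
      dump <- xgboost::xgb.dump(fitted$fit)
      hits <- regmatches(dump, regexpr("\\[[^<]+<", dump))
      unique(substr(hits, 2, nchar(hits) - 1))
    },
    stump = if (is.null(fitted$fit$feature)) character(0) else fitted$fit$feature,
    abort("split-usage is defined for tree learners only")
  )
}

# ---- AdaBoost.R2 (Drucker 1997) over rpart regression trees ----------------

fit_adaboost_r2 <- function(x, y, params) {
  n <- nrow(x)
  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_len(ncol(x)))
  df$.y <- y
  w <- rep(1 / n, n)
  trees <- list()
  betas <- numeric(0)
  for (m in seq_len(params$n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w,
                        control = rpart::rpart.control(
                          maxdepth = params$max_depth, cp = 0,
                          minsplit = max(5, floor(n / 20)), xval = 0))
    pred <- predict(fit, df)
    err <- abs(pred - y)
    emax <- max(err)
    if (emax <= .Machine$double.eps) {  # perfect fit: keep it, stop boosting
      trees[[m]] <- fit
      betas[m] <- 1e-10
      break
    }
    l <- switch(params$loss,
                linear = err / emax,
                square = (err / emax)^2,
                exponential = 1 - exp(-err / emax))
    ebar <- sum(w * l)
    if (ebar >= 0.5) break
    beta <- ebar / (1 - ebar)
    trees[[m]] <- fit
    betas[m] <- beta
    w <- w * beta^(1 - l)
    w <- w / sum(w)
  }
  if (length(trees) == 0) {  # weak learner never beat chance: fall back to mean
    return(list(trees = list(), betas = numeric(0), mean = mean(y),
                p = ncol(x)))
  }
  list(trees = trees, betas = betas, mean = mean(y), p = ncol(x))
}

predict_adaboost_r2 <- function(model, newx) {
  if (length(model$trees) == 0) return(rep(model$mean, nrow(newx)))
  df <- as.data.frame(newx)
  names(df) <- paste0("V", seq_len(ncol(newx)))
  preds <- vapply(model$trees, function(tr) predict(tr, df),
                  numeric(nrow(newx)))
  preds <- matrix(preds, nrow = nrow(newx))
  lw <- log(1 / model$betas)
  # weighted median across boosting rounds (Drucker's combination rule)
  apply_weighted_median(preds, lw)
}

apply_weighted_median <- function(preds, lw) {
  half <- sum(lw) / 2
  vapply(seq_len(nrow(preds)), function(i) {
    o <- order(preds[i, ])
    cum <- cumsum(lw[o])
    preds[i, o[which(cum >= half)[1]]]
  }, numeric(1))
}

# ---- exact regression stump (depth-1, squared error) -----------------------
# Best split by exhaustive scan over midpoints; deterministic tie-break toward
# the earlier column, then the smaller threshold. Used as the reference weak
# learner for exhaustive-subsample stability checks.

fit_stump <- function(x, y) {
  n <- nrow(x)
  base_sse <- sum((y - mean(y))^2)
  best <- list(feature = NULL, threshold = NA_real_, sse = base_sse,
               left = mean(y), right = mean(y), mean = mean(y))
  if (base_sse <= 0) return(best)
  for (j in seq_len(ncol(x))) {
    xv <- x[, j]
    cuts <- sort(unique(xv))
    if (length(cuts) < 2) next
    thr <- (cuts[-length(cuts)] + cuts[-1]) / 2
    for (t in thr) {
      l <- xv <= t
      sse <- sum((y[l] - mean(y[l]))^2) + sum((y[!l] - mean(y[!l]))^2)
      if (sse < best$sse - 1e-12) {
        best <- list(feature = colnames(x)[j], threshold = t, sse = sse,
                     left = mean(y[l]), right = mean(y[!l]), mean = mean(y))
      }
    }
  }
  best
}

predict_stump <- function(model, newx) {
  if (is.null(model$feature)) return(rep(model$mean, nrow(newx)))
  ifelse(newx[, model$feature] <= model$threshold, model$left, model$right)
}
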