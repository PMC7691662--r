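#' Stability-selection configuration
#'
#' Stability selection scores each feature by how often a depth-limited
#' boosted-tree regressor uses it (in at least one split) across many random
#' half-subsamples, sweeping tree depth 2-10 as the complexity (lambda) path.
#' Per-depth selection frequencies are aggregated over the path (maximum by
#' default) into a stability score in `[0, 1]`.
#'
#' @param depths Tree-depth lambda path (default 2:10).
#' @param n_subsamples Subsamples per depth (default 100).
#' @param fraction Subsample fraction of the training rows (default 0.5).
#' @param aggregation Combine per-depth frequencies by `"max"` (default) or
#'   `"mean"`.
#' @param learner `"xgboost"` (default) or `"stump"` (exact depth-1 stumps,
#'   used for exhaustive small-n verification).
#' @param nrounds,eta,min_child_weight,tree_method,max_bin Boosted-tree
#'   parameters for the inner fits; deliberately few rounds, since only
#'   split-usage indicators are needed, not converged fits.
#' @param gamma Minimum loss reduction for a split in the inner fits, on a
#'   unit-variance response (the response is standardised before each fit so
#'   the regulariser is scale-free). Without it every feature is eventually
#'   used by deep trees and all stability scores saturate at 1.
#' @param subsample_mode `"random"` (default) or `"exhaustive"` (enumerate all
#'   `choose(n, n * fraction)` subsamples; only sensible for n <= 12).
#' @param force_in_groups Feature groups always retained regardless of score
#'   (default the dose assignment).
#' @param seed Integer seed; subsample membership is drawn by subject id, so
#'   scores are invariant to row order.
#' @return A list of class `stability_config`.
#' @export
stability_config <- function(depths = 2:10, n_subsamples = 100, fraction = 0.5,
                             aggregation = c("max", "mean"),
                             learner = c("xgboost", "stump"),
                             nrounds = 20, eta = 0.3, min_child_weight = 5,
                             gamma = 4, tree_method = "hist", max_bin = 16,
                             subsample_mode = c("random", "exhaustive"),
                             force_in_groups = "dose",
                             seed = 1L) {
  assert_that(all(depths >= 1), "depths must be >= 1")
  assert_that(fraction > 0 && fraction <= 1, "fraction must lie in (0, 1]")
  assert_that(n_subsamples >= 1, "need at least one subsample")
  structure(list(depths = as.integer(depths),
                 n_subsamples = as.integer(n_subsamples), fraction = fraction,
                 aggregation = match.arg(aggregation),
                 learner = match.arg(learner),
                 nrounds = nrounds, eta = eta, gamma = gamma,
                 min_child_weight = min_child_weight,
                 tree_method = tree_method, max_bin = max_bin,
                 subsample_mode = match.arg(subsample_mode),
                 force_in_groups = force_in_groups,
                 seed = as.integer(seed)),
            class = "stability_config")
}

as_feature_matrix <- function(x) {
  if (inherits(x, "feature_matrix")) return(x)
  assert_that(is.matrix(x) && !is.null(colnames(x)),
              "x must be a feature_matrix or a named-column matrix")
  structure(list(x = x,
                 meta = tibble(column = colnames(x), feature = colnames(x),
                               level = NA_character_, group = NA_character_,
                               kind = "continuous")),
            class = "feature_matrix")
}

#' Stability scores over the depth path
#'
#' @param fm A [encode_features()] `feature_matrix` (or plain matrix with
#'   column names).
#' @param y Numeric response aligned with the rows of `fm` (the VHS at V2).
#' @param config A [stability_config()].
#' @return An object of class `stability_result`: a per-feature tibble of
#'   stability scores and per-depth selection frequencies, plus bookkeeping.
#'   Scores are at the source-feature level: a feature counts as selected in
#'   one fit if any of its encoded columns is used in at least one split.
#' @export
stability_scores <- function(fm, y, config = stability_config()) {
  fm <- as_feature_matrix(fm)
  n <- nrow(fm$x)
  assert_that(length(y) == n, "x and y are misaligned")
  assert_that(sd(y) > 0, "constant response")
  m <- max(2L, floor(n * config$fraction))
  assert_that(n >= m && m >= 2, "too few rows for the subsample fraction")

  ids <- rownames(fm$x) %||% as.character(seq_len(n))
  ord_ids <- sort(ids)
  features <- unique(fm$meta$feature)

  subsets <- NULL
  if (config$subsample_mode == "exhaustive") {
    assert_that(n <= 12, "exhaustive subsampling is limited to n <= 12")
    subsets <- combn(ord_ids, m, simplify = FALSE)
  }

  freq <- matrix(0, nrow = length(features), ncol = length(config$depths),
                 dimnames = list(features, paste0("depth_", config$depths)))
  withr::with_seed(derive_seed(config$seed, 59L), {
    for (di in seq_along(config$depths)) {
      d <- config$depths[di]
      draws <- subsets %||%
        replicate(config$n_subsamples, sample(ord_ids, m), simplify = FALSE)
      counts <- setNames(numeric(length(features)), features)
      for (sub in draws) {
        rows <- match(sub, ids)
        used <- fit_and_usage(fm$x[rows, , drop = FALSE], y[rows], d, config)
        sel <- unique(fm$meta$feature[fm$meta$column %in% used])
        counts[sel] <- counts[sel] + 1
      }
      freq[, di] <- counts / length(draws)
    }
  })

  score <- unname(if (config$aggregation == "max") apply(freq, 1, max)
                  else rowMeans(freq))
  group <- fm$meta$group[match(features, fm$meta$feature)]
  scores <- bind_cols(tibble(feature = features, group = group, score = score),
                      as_tibble(freq))
  structure(list(scores = scores, config = config, n = n,
                 force_in = features[group %in% config$force_in_groups],
                 chosen_threshold = NA_real_, selected = NULL,
                 sweep = NULL, baseline_cv_pcc = NA_real_),
            class = "stability_result")
}

fit_and_usage <- function(x, y, depth, config) {
  if (config$learner == "stump") {
    return(used_features(fit_learner(learner_stump(), x, y)))
  }
  spec <- learner_xgboost(max_depth = depth, eta = config$eta,
                          nrounds = config$nrounds, gamma = config$gamma,
                          min_child_weight = config$min_child_weight,
                          tree_method = config$tree_method,
                          max_bin = config$max_bin)
  ys <- (y - mean(y)) / sd(y)  # scale-free gamma regularisation
  used_features(fit_learner(spec, x, ys))
}

#' @export
print.stability_result <- function(x, ...) {
  cat("<stability_result>", nrow(x$scores), "features | aggregation:",
      x$config$aggregation, "\n")
  if (!is.na(x$chosen_threshold))
    cat("  threshold:", x$chosen_threshold, "->", length(x$selected),
        "selected features\n")
  invisible(x)
}

#' Select features at a stability threshold
#'
#' Returns the features whose stability score is at least `threshold`, in the
#' original column order, always including forced-in groups (the dose).
#'
#' @param result A [stability_scores()] result.
#' @param threshold Stability-score threshold in `[0, 1]`.
#' @return Character vector of feature names.
#' @export
select_features <- function(result, threshold) {
  assert_that(is_scalar_number(threshold) && threshold >= 0 && threshold <= 1,
              "threshold must lie in [0, 1]")
  sc <- result$scores
  sc$feature[sc$score >= threshold | sc$feature %in% result$force_in]
}

#' Choose the stability threshold by the two published criteria
#'
#' Candidate thresholds are screened by 10-fold cross-validated Pearson
#' correlation (PCC) of a boosted-tree model on the retained features:
#' eligible thresholds keep the CV PCC within `tolerance` of the best
#' attainable over the sweep — "not lowering the average PCC" — and never
#' below the all-features baseline minus `tolerance` (criterion 2); among the
#' eligible candidates the one retaining fewest features wins (criterion 1),
#' ties broken toward the larger threshold. The sweep table (feature count
#' and CV PCC per candidate) is stored for plotting.
#'
#' @inheritParams stability_scores
#' @param result A [stability_scores()] result.
#' @param candidates Candidate thresholds (default 0.50-0.95 by 0.05).
#' @param k Cross-validation folds.
#' @param tolerance Allowed CV-PCC drop below baseline (default 0.005).
#' @param learner `learner_spec` used for the screening fits.
#' @param seed Seed for the fold assignment (shared across candidates).
#' @return The `stability_result` updated with `chosen_threshold`, `selected`,
#'   `sweep` and `baseline_cv_pcc`.
#' @export
choose_threshold <- function(fm, y, result,
                             candidates = seq(0.5, 0.95, by = 0.05),
                             k = 10, tolerance = 0.005,
                             learner = learner_xgboost(), seed = 1L) {
  assert_that(length(candidates) > 0, "need at least one candidate threshold")
  fm <- as_feature_matrix(fm)
  folds <- make_folds(nrow(fm$x), k, seed)
  baseline <- cv_pcc(learner, fm$x, y, k = k, seed = seed, folds = folds)
  cache <- list()
  sweep <- purrr::map_dfr(sort(candidates), function(tau) {
    sel <- select_features(result, tau)
    if (length(sel) == 0)
      return(tibble(threshold = tau, n_features = 0L, cv_pcc = NA_real_))
    key <- paste(sel, collapse = "\r")
    if (is.null(cache[[key]])) {
      sub <- fm_subset(fm, sel)
      cache[[key]] <<- cv_pcc(learner, sub$x, y, k = k, seed = seed,
                              folds = folds)$mean_pcc
    }
    tibble(threshold = tau, n_features = length(sel), cv_pcc = cache[[key]])
  })
  best_cv <- suppressWarnings(max(sweep$cv_pcc, na.rm = TRUE))
  required <- max(baseline$mean_pcc, best_cv) - tolerance
  eligible <- sweep[!is.na(sweep$cv_pcc) &
                      sweep$cv_pcc >= required &
                      sweep$n_features > 0, ]
  if (nrow(eligible) == 0) {
    warn("no candidate threshold preserves the baseline CV PCC; returning 0")
    tau <- 0
  } else {
    eligible <- eligible[order(eligible$n_features, -eligible$threshold), ]
    tau <- eligible$threshold[1]
  }
  result$chosen_threshold <- tau
  result$selected <- select_features(result, tau)
  result$sweep <- sweep
  result$baseline_cv_pcc <- baseline$mean_pcc
  result
}
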