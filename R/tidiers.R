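#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a stability-selection result
#'
#' One row per feature: stability score, group, per-depth selection
#' frequencies and whether the feature survives the chosen threshold.
#'
#' @param x A `stability_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.stability_result <- function(x, ...) {
  out <- x$scores
  if (!is.null(x$selected)) out$selected <- out$feature %in% x$selected
  dplyr::arrange(out, dplyr::desc(.data$score))
}

#' @rdname tidy.stability_result
#' @export
glance.stability_result <- function(x, ...) {
  tibble(n_features = nrow(x$scores),
         chosen_threshold = x$chosen_threshold,
         n_selected = length(x$selected %||% character(0)),
         baseline_cv_pcc = x$baseline_cv_pcc,
         aggregation = x$config$aggregation,
         n_subsamples = x$config$n_subsamples)
}

#' Tidy a trained dose model
#'
#' Feature importances: xgboost gain, AdaBoost.R2 summed weak-learner
#' importance, or absolute elastic-net coefficients, aggregated to source
#' features.
#'
#' @param x A `dose_model`.
#' @param ... Unused.
#' @return Tibble `feature`, `importance`, sorted decreasing.
#' @export
tidy.dose_model <- function(x, ...) {
  imp <- switch(x$kind,
    xgboost = {
      # summed split gain per feature, parsed from the dump (robust for any
      # booster size, unlike xgb.importance in this xgboost generation)
      dump <- xgboost::xgb.dump(x$fit$fit, with_stats = TRUE)
      splits <- grep("gain=", dump, value = TRUE)
      feat <- sub("^.*\\[([^<]+)<.*$", "\\1", splits)
      gain <- as.numeric(sub("^.*gain=([-0-9.e+]+).*$", "\\1", splits))
      tot <- tapply(gain, feat, sum)
      tot / sum(tot)
    },
    adaboost = {
      vi <- lapply(x$fit$fit$trees, function(tr) tr$variable.importance)
      all <- unlist(vi)
      idx <- as.integer(sub("^V", "", names(all)))
      tapply(all, x$features[idx], sum)
    },
    elasticnet = {
      co <- as.matrix(stats::coef(x$fit$fit, s = "lambda.min"))[-1, 1]
      abs(co[co != 0])
    })
  cols <- tibble(column = names(imp), importance = as.numeric(imp))
  out <- dplyr::left_join(cols, x$meta[, c("column", "feature")],
                          by = "column")
  out$feature <- dplyr::coalesce(out$feature, out$column)
  out |>
    group_by(.data$feature) |>
    summarise(importance = sum(.data$importance), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @rdname tidy.dose_model
#' @export
glance.dose_model <- function(x, ...) {
  tibble(kind = x$kind, n_encoded_features = length(x$features),
         cv_pcc = x$cv_pcc, seed = x$seed)
}

#' @rdname tidy.dose_model
#' @export
glance.dose_pipeline <- function(x, ...) {
  rep <- tidyr::pivot_wider(x$report[, c("set", "pcc")],
                            names_from = "set", values_from = "pcc",
                            names_prefix = "pcc_")
  bind_cols(
    tibble(n_subjects = nrow(x$cohort), n_raw_features = nrow(x$schema),
           n_encoded = ncol(x$feature_matrix$x),
           threshold = x$stability$chosen_threshold,
           n_selected = length(x$stability$selected)),
    rep
  )
}
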