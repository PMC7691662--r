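#' Counterfactual VHS predictions under candidate doses
#'
#' For each subject, the feature vector is scored once per candidate dose with
#' the dose entry overwritten and every other feature untouched — the plug-in
#' counterfactual the recommendation rule consumes.
#'
#' @param model A [tune_and_train()] `dose_model` whose features include the
#'   dose column.
#' @param fm `feature_matrix` (or matrix) of subjects to score.
#' @param doses Candidate doses in mg (default 6, 10, 14).
#' @param dose_feature Name of the dose column (default `"dose"`).
#' @return Tibble `subject_id`, `dose`, `predicted_vhs` (long, one row per
#'   subject-dose pair).
#' @export
counterfactual_predictions <- function(model, fm, doses = c(6, 10, 14),
                                       dose_feature = "dose") {
  assert_that(length(doses) >= 1, "need at least one candidate dose")
  newx <- if (inherits(fm, "feature_matrix")) fm$x else fm
  assert_that(dose_feature %in% model$features,
              "model does not carry the dose feature")
  ids <- rownames(newx) %||% as.character(seq_len(nrow(newx)))
  purrr::map_dfr(sort(doses), function(d) {
    xd <- newx
    xd[, dose_feature] <- d
    tibble(subject_id = ids, dose = d,
           predicted_vhs = predict(model, xd))
  })
}

# vectorised three-branch rule; pred is n x d (columns = ascending doses)
categorize_doses <- function(pred, baseline, improve_thr = 0.1,
                             indiff_thr = 0.05) {
  doses <- as.numeric(colnames(pred))
  cols <- as.data.frame(pred)
  best <- do.call(pmax, cols)
  spread <- best - do.call(pmin, cols)
  argmax_dose <- doses[max.col(pred, ties.method = "first")]
  category <- ifelse(best - baseline <= improve_thr, "no_benefit",
              ifelse(spread < indiff_thr, "lower_dose_sufficient",
              ifelse(argmax_dose == max(doses), "highest_dose_optimal",
                     "lower_dose_sufficient")))
  recommended <- ifelse(category == "no_benefit", NA_real_,
                 ifelse(category == "lower_dose_sufficient" & spread < indiff_thr,
                        min(doses), argmax_dose))
  tibble(category = factor(category,
                           levels = c("no_benefit", "lower_dose_sufficient",
                                      "highest_dose_optimal")),
         recommended_dose = recommended)
}

#' Recommend a dose from counterfactual predictions
#'
#' Decision rule, applied in order: (1) if the best predicted VHS improves on
#' the measured baseline VHS by no more than `improve_thr` (default 0.1 VHS
#' in 45 days), the subject cannot benefit — no dose; (2) otherwise, if the
#' spread (max - min) of the predicted VHS across the candidate doses is
#' below `indiff_thr` (default 0.05), the doses are interchangeable and the
#' lowest suffices; (3) otherwise the dose with the highest predicted VHS is
#' optimal (ties toward the lowest such dose) — the top candidate yields
#' category `highest_dose_optimal`, a lower argmax `lower_dose_sufficient`.
#'
#' @param map Named numeric: predicted VHS per candidate dose (names = doses
#'   in mg).
#' @param baseline_vhs Measured baseline (V1) VHS on the same frozen scale.
#' @param improve_thr,indiff_thr Decision thresholds (VHS units).
#' @return One-row tibble: `category`, `recommended_dose`, and the predicted
#'   VHS per dose (`pred_<dose>` columns).
#' @export
#' @examples
#' recommend_dose(c(`6` = 0.20, `10` = 0.30, `14` = 0.45), baseline_vhs = 0)
recommend_dose <- function(map, baseline_vhs, improve_thr = 0.1,
                           indiff_thr = 0.05) {
  assert_that(length(map) >= 1 && !is.null(names(map)), "map must be nonempty and named by dose")
  assert_that(improve_thr >= 0 && indiff_thr >= 0, "thresholds must be >= 0")
  ord <- order(as.numeric(names(map)))
  pred <- matrix(map[ord], nrow = 1,
                 dimnames = list(NULL, names(map)[ord]))
  out <- categorize_doses(pred, baseline_vhs, improve_thr, indiff_thr)
  preds <- setNames(as.list(pred[1, ]), paste0("pred_", colnames(pred)))
  bind_cols(out, as_tibble(preds))
}

#' Per-subject dose recommendations for a scored set
#'
#' Runs [counterfactual_predictions()] and the [recommend_dose()] rule over
#' every subject.
#'
#' @inheritParams counterfactual_predictions
#' @param baseline_vhs Named numeric vector of measured baseline VHS
#'   (names = subject ids) or unnamed vector aligned with `fm` rows.
#' @param improve_thr,indiff_thr Decision thresholds (VHS units).
#' @return Tibble of class `dose_recommendations`: `subject_id`,
#'   `baseline_vhs`, `pred_<dose>` columns, `category`, `recommended_dose`.
#' @export
recommend_doses <- function(model, fm, baseline_vhs, doses = c(6, 10, 14),
                            improve_thr = 0.1, indiff_thr = 0.05,
                            dose_feature = "dose") {
  cf <- counterfactual_predictions(model, fm, doses, dose_feature)
  wide <- tidyr::pivot_wider(cf, names_from = "dose",
                             values_from = "predicted_vhs")
  pred <- as.matrix(wide[, -1, drop = FALSE])
  rownames(pred) <- wide$subject_id
  base <- if (!is.null(names(baseline_vhs)))
    baseline_vhs[wide$subject_id] else baseline_vhs
  assert_that(!anyNA(base), "baseline VHS missing for some subjects")
  cats <- categorize_doses(pred, base, improve_thr, indiff_thr)
  out <- bind_cols(
    tibble(subject_id = wide$subject_id, baseline_vhs = unname(base)),
    setNames(as_tibble(pred), paste0("pred_", colnames(pred))),
    cats
  )
  class(out) <- c("dose_recommendations", class(out))
  attr(out, "thresholds") <- c(improve = improve_thr, indifference = indiff_thr)
  out
}

#' Cohort-level recommendation summary
#'
#' Counts and percentages (one decimal) per recommendation category.
#'
#' @param recommendations A [recommend_doses()] tibble.
#' @return Tibble `category`, `n`, `pct`.
#' @export
summarize_recommendations <- function(recommendations) {
  assert_that(nrow(recommendations) > 0, "no recommendations to summarise")
  counts <- table(recommendations$category)
  tibble(category = names(counts), n = as.integer(counts),
         pct = round(100 * as.integer(counts) / nrow(recommendations), 1))
}
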