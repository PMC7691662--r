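#' Run the full dose-prediction pipeline on a synthetic cohort
#'
#' End-to-end orchestration: generate the cohort (with missingness and
#' out-of-range writing mistakes), score the composite VHS at every visit,
#' clean/impute/encode the baseline panel (appending baseline VHS as a
#' feature), split into training / arm-stratified test / random validation,
#' screen features by stability selection over the depth path, choose the
#' threshold by the two published criteria, tune and train the boosted-tree
#' response model, evaluate by PCC on all three sets, and issue per-subject
#' counterfactual dose recommendations for the held-out subjects.
#'
#' @param config A [sim_config()].
#' @param seed Master seed (defaults to `config$seed`); every stochastic stage
#'   derives its own stream from it.
#' @param stability A [stability_config()] (its seed is overridden by `seed`).
#' @param candidates,tolerance Threshold-choice settings, see
#'   [choose_threshold()].
#' @param grid Hyperparameter grid for [tune_and_train()].
#' @param k Cross-validation folds.
#' @param test_per_arm,n_validation Split scheme, see [split_cohort()].
#' @param doses Candidate doses for recommendation (default 6/10/14 mg).
#' @param improve_thr,indiff_thr Recommendation thresholds (VHS units).
#' @return A list of class `dose_pipeline`: the processed cohort and schema,
#'   ground truth, VHS scores, split, stability result, trained model,
#'   evaluation report, recommendations and their summary.
#' @export
run_dose_pipeline <- function(config = sim_config(), seed = NULL,
                              stability = stability_config(),
                              candidates = seq(0.5, 0.95, by = 0.05),
                              tolerance = 0.005, grid = NULL, k = 10,
                              test_per_arm = 7, n_validation = 30,
                              doses = setdiff(config$doses, 0),
                              improve_thr = 0.1, indiff_thr = 0.05) {
  seed <- seed %||% config$seed
  sim <- generate_cohort(config, seed = seed)
  raw <- inject_missingness(sim$cohort, sim$schema, config$missing_rate,
                            seed = derive_seed(seed, 2L))
  raw <- inject_errors(raw, sim$schema, config$error_rate,
                       seed = derive_seed(seed, 3L))

  scores <- score_vhs(raw, orientation = config$orientation)
  cleaned <- clean_cohort(raw, sim$schema)
  log <- cleaning_log(cleaned)
  imputed <- impute_mean(cleaned, sim$schema)
  aug <- add_baseline_vhs(imputed, sim$schema, scores)
  fm <- encode_features(aug$cohort, aug$schema)
  split <- split_cohort(aug$cohort, test_per_arm, n_validation, seed = seed)

  v2 <- scores[scores$visit == "v2", ]
  y_all <- setNames(v2$vhs, v2$subject_id)
  stability$seed <- seed

  stage <- fit_model_stage(fm, y_all, split, stability, candidates, tolerance,
                           grid, k, seed)

  v1 <- scores[scores$visit == "v1", ]
  base_vhs <- setNames(v1$vhs, v1$subject_id)
  holdout <- c(split$test, split$validation)
  recs <- recommend_doses(stage$model, fm_rows(fm, holdout),
                          base_vhs[holdout], doses = doses,
                          improve_thr = improve_thr, indiff_thr = indiff_thr)

  structure(list(
    config = config, seed = seed,
    cohort = aug$cohort, schema = aug$schema, truth = sim$truth,
    scores = scores, cleaning_log = log, feature_matrix = fm,
    split = split, stability = stage$stability, model = stage$model,
    report = stage$report, y = y_all,
    recommendations = recs,
    summary = summarize_recommendations(recs)
  ), class = "dose_pipeline")
}

fm_rows <- function(fm, ids) {
  structure(list(x = fm$x[ids, , drop = FALSE], meta = fm$meta),
            class = "feature_matrix")
}

# selection + threshold + tuning + evaluation on a given split
fit_model_stage <- function(fm, y_all, split, stability, candidates,
                            tolerance, grid, k, seed) {
  fm_train <- fm_rows(fm, split$train)
  y_train <- y_all[split$train]
  stab <- stability_scores(fm_train, y_train, stability)
  stab <- choose_threshold(fm_train, y_train, stab, candidates = candidates,
                           k = k, tolerance = tolerance, seed = seed)
  fm_sel <- fm_subset(fm, stab$selected)
  model <- tune_and_train(fm_rows(fm_sel, split$train), y_train,
                          grid = grid, k = k, seed = seed)
  report <- tibble(
    set = c("training_cv", "test", "validation"),
    n = c(length(split$train), length(split$test), length(split$validation)),
    pcc = c(model$cv_pcc,
            pcc(y_all[split$test],
                predict(model, fm_rows(fm_sel, split$test))),
            pcc(y_all[split$validation],
                predict(model, fm_rows(fm_sel, split$validation))))
  )
  list(stability = stab, model = model, report = report)
}

#' @export
print.dose_pipeline <- function(x, ...) {
  cat("<dose_pipeline> n =", nrow(x$cohort), "| features:",
      nrow(x$schema), "raw /", ncol(x$feature_matrix$x), "encoded\n")
  cat("  threshold:", x$stability$chosen_threshold, "->",
      length(x$stability$selected), "selected\n")
  print(x$report)
  print(x$summary)
  invisible(x)
}

#' Retrain after removing feature groups
#'
#' Reproduces the published ablation protocol: drop all features of the named
#' groups (e.g. invasive blood tests, then costly OCT imaging), rerun
#' stability selection with a fresh threshold choice on the same training
#' split, retrain, and report training-CV / test / validation PCC side by
#' side with the original model.
#'
#' @param fit A [run_dose_pipeline()] result.
#' @param drop Named list of character vectors of groups to remove per
#'   ablation; the original (drop-nothing) model is always reported first.
#' @param candidates,tolerance,grid,k As in [run_dose_pipeline()].
#' @return Tibble `ablation`, `n_pool` (raw features eligible), `threshold`,
#'   `n_selected`, `pcc_training_cv`, `pcc_test`, `pcc_validation`; fitted
#'   stage objects attached as attribute `"stages"`.
#' @export
ablate_feature_groups <- function(fit,
                                  drop = list(no_blood = "blood",
                                              no_blood_oct = c("blood", "oct")),
                                  candidates = seq(0.5, 0.95, by = 0.05),
                                  tolerance = 0.005, grid = NULL, k = 10) {
  assert_that(inherits(fit, "dose_pipeline"), "fit must be a dose_pipeline")
  bad <- vapply(drop, function(g) "dose" %in% g, logical(1))
  assert_that(!any(bad), "the dose group cannot be ablated")
  unknown <- setdiff(unique(unlist(drop)), unique(fit$schema$group))
  assert_that(length(unknown) == 0,
              paste("unknown groups:", paste(unknown, collapse = ", ")))

  row_for <- function(name, stage, n_pool) {
    tibble(ablation = name, n_pool = n_pool,
           threshold = stage$stability$chosen_threshold,
           n_selected = length(stage$stability$selected),
           pcc_training_cv = stage$report$pcc[1],
           pcc_test = stage$report$pcc[2],
           pcc_validation = stage$report$pcc[3])
  }
  stages <- list(original = list(stability = fit$stability, model = fit$model,
                                 report = fit$report))
  out <- row_for("original", stages$original, nrow(fit$schema))
  for (nm in names(drop)) {
    keep <- fit$schema$name[!(fit$schema$group %in% drop[[nm]])]
    fm_d <- fm_subset(fit$feature_matrix, keep)
    stability <- fit$stability$config
    stage <- fit_model_stage(fm_d, fit$y, fit$split, stability,
                             candidates, tolerance, grid, k, fit$seed)
    stages[[nm]] <- stage
    out <- bind_rows(out, row_for(nm, stage, length(keep)))
  }
  attr(out, "stages") <- stages
  out
}
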