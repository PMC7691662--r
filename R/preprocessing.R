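#' Clean a cohort against its schema
#'
#' Operationalises "obvious writing mistakes": any cell outside its feature's
#' declared valid range (continuous), not among the declared levels
#' (discrete), or containing an undeclared option (multi-choice) is set
#' missing. Every change is recorded in a cleaning log attached as attribute
#' `"cleaning_log"` (tibble `subject_id`, `feature`, `value`). Already-missing
#' cells are not logged. Structural columns (`subject_id`, `arm`, follow-up
#' eye indexes) pass through untouched; any other column absent from the
#' schema is an error.
#'
#' @param cohort Subject table.
#' @param schema A [feature_schema()] covering the feature columns.
#' @return The cleaned cohort.
#' @export
clean_cohort <- function(cohort, schema) {
  structural <- c("subject_id", "arm",
                  grep("^(tsefs|vp|mpod|st)_v[23]$", names(cohort), value = TRUE))
  unknown <- setdiff(names(cohort), c(structural, schema$name))
  assert_that(length(unknown) == 0,
              paste("columns absent from schema:", paste(unknown, collapse = ", ")))
  log <- list()
  feats <- schema[schema$name %in% names(cohort), ]
  for (i in seq_len(nrow(feats))) {
    f <- feats$name[i]
    v <- cohort[[f]]
    bad <- switch(feats$kind[i],
      continuous = {
        v <- suppressWarnings(as.numeric(v))
        !is.na(cohort[[f]]) & (!is.finite(v) | v < feats$min[i] | v > feats$max[i])
      },
      discrete = !is.na(v) & !(v %in% feats$options[[i]]),
      multi_choice = !is.na(v) & vapply(v, function(cell) {
        opts <- split_multi(cell)
        length(opts) > 0 && !all(opts %in% feats$options[[i]])
      }, logical(1))
    )
    if (any(bad)) {
      log[[f]] <- tibble(subject_id = cohort$subject_id[bad], feature = f,
                         value = as.character(cohort[[f]][bad]))
    }
    if (feats$kind[i] == "continuous") {
      v[bad] <- NA_real_
      cohort[[f]] <- v  # coerced numeric, violations blanked
    } else if (any(bad)) {
      cohort[[f]][bad] <- NA_character_
    }
  }
  log <- if (length(log)) bind_rows(log) else
    tibble(subject_id = character(), feature = character(), value = character())
  attr(cohort, "cleaning_log") <- log
  cohort
}

#' @rdname clean_cohort
#' @export
cleaning_log <- function(cohort) {
  attr(cohort, "cleaning_log") %||%
    tibble(subject_id = character(), feature = character(), value = character())
}

#' Mean-impute missing values
#'
#' Missing continuous cells are replaced by the mean of all non-missing cases
#' of the feature; non-missing cells are untouched. Categorical analogues:
#' missing discrete cells take the most frequent level, missing multi-choice
#' answers become the empty set (which multi-hot encodes as all zeros).
#'
#' @inheritParams clean_cohort
#' @return The imputed cohort.
#' @export
impute_mean <- function(cohort, schema) {
  feats <- schema[schema$name %in% names(cohort), ]
  for (i in seq_len(nrow(feats))) {
    f <- feats$name[i]
    v <- cohort[[f]]
    if (!anyNA(v)) next
    cohort[[f]] <- switch(feats$kind[i],
      continuous = {
        assert_that(!all(is.na(v)), paste("fully-missing column:", f))
        v[is.na(v)] <- mean(v, na.rm = TRUE)
        v
      },
      discrete = {
        assert_that(!all(is.na(v)), paste("fully-missing column:", f))
        v[is.na(v)] <- stat_mode(v)
        v
      },
      multi_choice = {
        v[is.na(v)] <- ""
        v
      }
    )
  }
  cohort
}

#' Encode cohort features into a numeric matrix
#'
#' Continuous features pass through unchanged; each discrete feature with k
#' declared levels becomes k indicator columns with row sum exactly 1; each
#' multi-choice feature with m options becomes m indicator columns with row
#' sums in `[0, m]`. Encoding follows schema order; a value outside the
#' declared levels/options is an error (signalled, never silently dropped).
#'
#' @inheritParams clean_cohort
#' @return An object of class `feature_matrix`: list with the numeric matrix
#'   `x` (subjects x encoded columns, row names = subject ids) and column
#'   metadata `meta` (tibble `column`, `feature`, `level`, `group`, `kind`).
#' @export
encode_features <- function(cohort, schema) {
  feats <- schema[schema$name %in% names(cohort), ]
  blocks <- vector("list", nrow(feats))
  metas <- vector("list", nrow(feats))
  for (i in seq_len(nrow(feats))) {
    f <- feats$name[i]
    v <- cohort[[f]]
    assert_that(!anyNA(v), paste("missing values remain in", f,
                                 "- clean and impute first"))
    if (feats$kind[i] == "continuous") {
      m <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, f))
      meta <- tibble(column = f, feature = f, level = NA_character_)
    } else {
      opts <- feats$options[[i]]
      if (feats$kind[i] == "discrete") {
        bad <- unique(v[!(v %in% opts)])
        assert_that(length(bad) == 0,
                    paste0("unseen level in ", f, ": ", paste(bad, collapse = ", ")))
        m <- outer(v, opts, "==") * 1
      } else {
        sets <- lapply(v, split_multi)
        bad <- setdiff(unique(unlist(sets)), opts)
        assert_that(length(bad) == 0,
                    paste0("unseen option in ", f, ": ", paste(bad, collapse = ", ")))
        m <- t(vapply(sets, function(s) as.numeric(opts %in% s),
                      numeric(length(opts))))
      }
      colnames(m) <- paste(f, opts, sep = "=")
      meta <- tibble(column = colnames(m), feature = f, level = opts)
    }
    meta$group <- feats$group[i]
    meta$kind <- feats$kind[i]
    blocks[[i]] <- m
    metas[[i]] <- meta
  }
  x <- do.call(cbind, blocks)
  if ("subject_id" %in% names(cohort)) rownames(x) <- cohort$subject_id
  structure(list(x = x, meta = bind_rows(metas)), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix>", nrow(x$x), "subjects x", ncol(x$x),
      "encoded columns from", dplyr::n_distinct(x$meta$feature),
      "features\n")
  invisible(x)
}

#' @export
as.matrix.feature_matrix <- function(x, ...) x$x

#' @export
dim.feature_matrix <- function(x) dim(x$x)

# subset a feature_matrix to the encoded columns of given source features
fm_subset <- function(fm, features) {
  keep <- fm$meta$feature %in% features
  structure(list(x = fm$x[, fm$meta$column[keep], drop = FALSE],
                 meta = fm$meta[keep, ]), class = "feature_matrix")
}

#' Split a cohort into training / test / validation sets
#'
#' The test set is stratified by arm with an equal per-arm count; the
#' validation set is drawn uniformly from the remaining subjects; training is
#' the rest. Defaults reproduce an 8:1:1-style split of 303 subjects into
#' 245 / 28 / 30.
#'
#' @param cohort Subject table with `subject_id` and `arm` columns.
#' @param test_per_arm Test subjects drawn per arm (default 7; 28 at 4 arms).
#' @param n_validation Validation-set size (default 30).
#' @param seed Integer seed.
#' @return A list of class `split_index` with character id vectors `train`,
#'   `test`, `validation` plus the scheme parameters.
#' @export
split_cohort <- function(cohort, test_per_arm = 7, n_validation = 30, seed = 1L) {
  assert_that(all(c("subject_id", "arm") %in% names(cohort)),
              "cohort needs subject_id and arm columns")
  arms <- sort(unique(cohort$arm))
  withr::with_seed(derive_seed(seed, 41L), {
    test <- character(0)
    for (a in arms) {
      ids <- sort(cohort$subject_id[cohort$arm == a])
      assert_that(length(ids) >= test_per_arm,
                  paste("arm", a, "smaller than test_per_arm"))
      test <- c(test, sample(ids, test_per_arm))
    }
    rest <- sort(setdiff(cohort$subject_id, test))
    assert_that(length(rest) >= n_validation,
                "validation request exceeds remaining subjects")
    validation <- if (n_validation > 0) sample(rest, n_validation) else character(0)
    train <- setdiff(rest, validation)
  })
  structure(list(train = train, test = test, validation = validation,
                 seed = seed, test_per_arm = test_per_arm,
                 n_validation = n_validation),
            class = "split_index")
}

#' @export
print.split_index <- function(x, ...) {
  cat("<split_index> train:", length(x$train), "test:", length(x$test),
      "validation:", length(x$validation), "\n")
  invisible(x)
}

#' Append the baseline VHS as a model feature
#'
#' The trial's selected-feature lists place the baseline composite score
#' itself among the predictors, so the pipeline appends the V1 VHS to the
#' feature panel (group `eye`) after scoring.
#'
#' @param cohort Subject table.
#' @param schema Matching [feature_schema()].
#' @param scores A `vhs_scores` tibble from [score_vhs()].
#' @return List with the extended `cohort` and `schema`.
#' @export
add_baseline_vhs <- function(cohort, schema, scores) {
  v1 <- scores[scores$visit == "v1", ]
  cohort$vhs_v1 <- v1$vhs[match(cohort$subject_id, v1$subject_id)]
  row <- tibble(name = "vhs_v1", kind = "continuous", group = "eye",
                min = -10, max = 10, options = list(NULL))
  for (extra in setdiff(names(schema), names(row))) row[[extra]] <- NA
  schema <- feature_schema(bind_rows(as_tibble(schema), row))
  list(cohort = cohort, schema = schema)
}
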