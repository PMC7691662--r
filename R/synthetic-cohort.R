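#' Generate a synthetic randomized-trial cohort with known ground truth
#'
#' Emits one row per subject carrying the arm/dose assignment, the four eye
#' indexes (TSEFS, VP, MPOD, Schirmer test) at visits V1 (baseline), V2
#' (45 days) and V3 (90 days), and the full baseline feature panel declared by
#' [build_sim_schema()]. The planted causal structure acts on the V2/V3 eye
#' indexes themselves: the target VHS change for a subject,
#' `dose_response[arm] + sum(effects * z(informative features)) +
#' responsiveness + noise`, is distributed equally across the four oriented,
#' transformed VHS components, so the composite-score module sits on the
#' causal path. With `noise_sd = 0` and no planted effects the per-arm V2
#' VHS shift equals `dose_response[arm]` exactly.
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A list of class `synthetic_cohort` with elements `cohort` (tibble,
#'   one row per subject), `schema` ([feature_schema()]) and `truth` (list of
#'   class `synthetic_truth`: informative features and coefficients, latent
#'   per-subject responsiveness, expected VHS change under every candidate
#'   dose, realized baseline VHS, the internal VHS transform parameters, and
#'   the oracle prediction ceiling for VHS at V2).
#' @export
generate_cohort <- function(config = sim_config(), seed = NULL) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  seed <- seed %||% config$seed
  schema <- build_sim_schema(config)
  eff <- config$effect_sizes
  if (length(eff)) {
    bad <- setdiff(names(eff), schema$name)
    assert_that(length(bad) == 0,
                paste("effect on undeclared feature(s):",
                      paste(bad, collapse = ", ")))
    kinds <- schema$kind[match(names(eff), schema$name)]
    assert_that(all(kinds == "continuous"),
                "planted effects are supported on continuous features only")
  }

  withr::with_seed(derive_seed(seed, 11L), {
    n <- config$n_subjects
    subject_id <- sprintf("S%04d", seq_len(n))

    # balanced arm assignment up to remainder, then shuffled
    doses <- config$doses
    base <- rep(doses, length.out = n)
    dose <- sample(base)
    arm <- arm_label(dose)

    feat_schema <- schema[schema$group != "dose", ]
    cols <- purrr::pmap(feat_schema, draw_feature, n = n)
    names(cols) <- feat_schema$name
    cohort <- tibble(subject_id = subject_id, arm = arm, dose = dose,
                     !!!cols)

    # internal V1 transform: same convention the scoring module uses
    params <- fit_vhs_transforms(
      tibble(tsefs = cohort$tsefs_v1, vp = cohort$vp_v1,
             mpod = cohort$mpod_v1, st = cohort$st_v1),
      orientation = config$orientation
    )

    # planted linear signal on standardized informative features
    signal <- rep(0, n)
    for (nm in names(eff)) {
      i <- match(nm, schema$name)
      mo <- dist_moments(schema$dist[i], schema$p1[i], schema$p2[i])
      signal <- signal + eff[[nm]] * (cohort[[nm]] - mo[1]) / mo[2]
    }
    responsiveness <- rnorm(n, 0, config$responsiveness_sd)

    dr <- config$dose_response
    expected_delta <- sapply(as.character(config$doses),
                             function(d) dr[[d]] + signal + responsiveness)
    colnames(expected_delta) <- as.character(config$doses)

    delta_v2 <- expected_delta[cbind(seq_len(n), match(as.character(dose),
                                                       colnames(expected_delta)))] +
      rnorm(n, 0, config$noise_sd)
    delta_v3 <- expected_delta[cbind(seq_len(n), match(as.character(dose),
                                                       colnames(expected_delta)))] +
      rnorm(n, 0, config$noise_sd)

    cohort <- shift_eye_indexes(cohort, params, delta_v2, "v2")
    cohort <- shift_eye_indexes(cohort, params, delta_v3, "v3")

    vhs_v1 <- aggregate_vhs(
      tibble(tsefs = cohort$tsefs_v1, vp = cohort$vp_v1,
             mpod = cohort$mpod_v1, st = cohort$st_v1), params)$vhs
    vhs_v2 <- vhs_v1 + delta_v2
    # ceiling of feature-based prediction: latent responsiveness and residual
    # noise are unlearnable, so the oracle predictor is baseline VHS + arm
    # effect + planted feature signal
    feat_pred <- vhs_v1 + dr[as.character(dose)] + signal
    ceiling_pcc <- if (config$noise_sd > 0 || config$responsiveness_sd > 0)
      cor(feat_pred, vhs_v2)
    else 1.0

    truth <- structure(list(
      informative_features = names(eff),
      coefficients = eff,
      responsiveness = setNames(responsiveness, subject_id),
      expected_delta = as_tibble(expected_delta) |>
        mutate(subject_id = subject_id, .before = 1),
      realized_delta_v2 = setNames(delta_v2, subject_id),
      vhs_v1 = setNames(vhs_v1, subject_id),
      transform_params = params,
      oracle_ceiling = ceiling_pcc
    ), class = "synthetic_truth")

    structure(list(cohort = cohort, schema = schema, truth = truth),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$cohort), "subjects,",
      nrow(x$schema), "schema features,",
      length(x$truth$informative_features), "informative\n")
  invisible(x)
}

draw_feature <- function(name, kind, group, min, max, options, probs,
                         dist, p1, p2, n, ...) {
  switch(dist,
    normal = pmin(pmax(rnorm(n, p1, p2), min), max),
    lognormal = pmin(pmax(rlnorm(n, p1, p2), min), max),
    gamma_ms = {
      shape <- (p1 / p2)^2
      pmin(pmax(stats::rgamma(n, shape = shape, scale = p2^2 / p1), min), max)
    },
    categorical = sample(options, n, replace = TRUE,
                         prob = probs %||% NULL),
    multihot = {
      k <- length(options)
      picks <- matrix(runif(n * k) < p1, n, k)
      apply(picks, 1, function(z) join_multi(options[z]))
    },
    abort(paste("unknown generator distribution:", dist))
  )
}

dist_moments <- function(dist, p1, p2) {
  switch(dist,
    normal = c(p1, p2),
    lognormal = {
      m <- exp(p1 + p2^2 / 2)
      c(m, m * sqrt(exp(p2^2) - 1))
    },
    gamma_ms = c(p1, p2),
    abort("effects require a continuous feature with known moments")
  )
}

# add delta to each oriented transformed component so the VHS shift is exact
shift_eye_indexes <- function(cohort, params, delta, visit) {
  o <- params$orientation
  cohort[[paste0("tsefs_", visit)]] <-
    cohort$tsefs_v1 + o[["tsefs"]] * delta * params$scale[["tsefs"]]
  cohort[[paste0("vp_", visit)]] <-
    cohort$vp_v1 + o[["vp"]] * delta * params$scale[["vp"]]
  cohort[[paste0("mpod_", visit)]] <-
    cohort$mpod_v1 + o[["mpod"]] * delta * params$scale[["mpod"]]
  cohort[[paste0("st_", visit)]] <-
    cohort$st_v1 + o[["st"]] * delta * (params$st_max - params$st_min)
  cohort
}

maskable_features <- function(cohort, schema) {
  setdiff(intersect(schema$name, names(cohort)),
          schema$name[schema$group %in% c("eye", "dose")])
}

#' Inject missing values into maskable baseline cells
#'
#' Eye indexes and the dose assignment are never masked. Each maskable cell is
#' set missing independently with probability `rate`; the mask is reproducible
#' from `seed` and attached as attribute `"mask"` (a tibble of
#' `subject_id`/`feature` positions).
#'
#' @param cohort Subject table from [generate_cohort()].
#' @param schema The matching [feature_schema()].
#' @param rate Fraction of maskable cells to set missing, in `[0, 1]`.
#' @param seed Integer seed.
#' @return The cohort with missing cells (`NA`).
#' @export
inject_missingness <- function(cohort, schema, rate, seed = 1L) {
  assert_that(is_scalar_number(rate) && rate >= 0 && rate <= 1,
              "rate must lie in [0, 1]")
  feats <- maskable_features(cohort, schema)
  mask_log <- list()
  withr::with_seed(derive_seed(seed, 23L), {
    for (f in feats) {
      hit <- runif(nrow(cohort)) < rate
      if (any(hit)) {
        cohort[[f]][hit] <- if (is.numeric(cohort[[f]])) NA_real_ else NA_character_
        mask_log[[f]] <- tibble(subject_id = cohort$subject_id[hit], feature = f)
      }
    }
  })
  attr(cohort, "mask") <- bind_rows(mask_log)
  cohort
}

#' Inject out-of-range "writing mistakes"
#'
#' Selected non-missing baseline cells are replaced by values that violate the
#' schema: continuous cells get a value strictly outside the declared range
#' (for example a weight of 1640 kg), discrete cells an undeclared level,
#' multi-choice cells an undeclared option. Eye indexes and dose are never
#' corrupted. Corrupted positions are reproducible from `seed` and attached as
#' attribute `"corruptions"`.
#'
#' @inheritParams inject_missingness
#' @param rate Fraction of eligible cells to corrupt.
#' @return The corrupted cohort.
#' @export
inject_errors <- function(cohort, schema, rate, seed = 1L) {
  assert_that(is_scalar_number(rate) && rate >= 0 && rate <= 1,
              "rate must lie in [0, 1]")
  feats <- maskable_features(cohort, schema)
  sch <- schema[match(feats, schema$name), ]
  assert_that(all(sch$kind != "continuous" |
                    (is.finite(sch$min) & is.finite(sch$max))),
              "every corruptible continuous feature needs a declared range")
  corr_log <- list()
  withr::with_seed(derive_seed(seed, 37L), {
    for (i in seq_along(feats)) {
      f <- feats[i]
      ok <- !is.na(cohort[[f]])
      hit <- ok & (runif(nrow(cohort)) < rate)
      if (!any(hit)) next
      k <- sum(hit)
      bad <- switch(sch$kind[i],
        continuous = {
          lo <- sch$min[i]; hi <- sch$max[i]; span <- hi - lo
          above <- runif(k) < 0.5
          ifelse(above, hi + span * runif(k, 0.5, 10),
                 lo - span * runif(k, 0.5, 10))
        },
        discrete = rep("INVALID_ENTRY", k),
        multi_choice = vapply(cohort[[f]][hit], function(v)
          join_multi(c(split_multi(v), "opt_undeclared")), character(1))
      )
      cohort[[f]][hit] <- bad
      corr_log[[f]] <- tibble(subject_id = cohort$subject_id[hit],
                              feature = f, value = as.character(bad))
    }
  })
  attr(cohort, "corruptions") <- bind_rows(corr_log)
  cohort
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `cohort.csv` (one row per subject; missing cells empty), a schema
#' JSON and a ground-truth JSON into `dir`.
#'
#' @param sim A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE, na = "")
  write_schema_json(sim$schema, file.path(dir, "schema.json"))
  tr <- sim$truth
  jsonlite::write_json(list(
    informative_features = tr$informative_features,
    coefficients = as.list(tr$coefficients),
    responsiveness = as.list(tr$responsiveness),
    oracle_ceiling = tr$oracle_ceiling
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
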