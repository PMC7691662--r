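#' Fit the visual-health-score component transforms
#'
#' The composite visual health score (VHS) averages four transformed eye
#' indexes. TSEFS, VP and MPOD are approximately normal at baseline and are
#' z-score transformed (sample, n-1, SD convention); the Schirmer test is
#' right-skewed and is min-max scaled to `[0, 1]` on the baseline range. Each
#' component carries an orientation sign: +1 keeps higher-is-better, -1 flips
#' (TSEFS counts symptoms, so more is worse and its default orientation is
#' -1). Parameters are fit once on baseline (V1) data pooled across arms and
#' frozen, so VHS at later visits is measured on a common scale.
#'
#' @param eye A data frame with numeric columns `tsefs`, `vp`, `mpod`, `st`
#'   (baseline values, one row per subject).
#' @param orientation Named signs for the four components.
#' @return An object of class `vhs_transform`: z-score centers/scales for
#'   TSEFS/VP/MPOD, min/max bounds for ST, the orientation vector, the fit
#'   visit label and the SD convention.
#' @export
#' @examples
#' params <- fit_vhs_transforms(
#'   data.frame(tsefs = c(5, 9, 7), vp = c(90, 100, 110),
#'              mpod = c(0.4, 0.5, 0.6), st = c(0, 10, 20)))
#' params$center[["tsefs"]]
fit_vhs_transforms <- function(eye,
                               orientation = c(tsefs = -1, vp = 1,
                                               mpod = 1, st = 1)) {
  comp <- c("tsefs", "vp", "mpod", "st")
  assert_that(all(comp %in% names(eye)), "eye table needs tsefs, vp, mpod, st")
  assert_that(nrow(eye) >= 2, "need at least 2 subjects to fit transforms")
  assert_that(all(sort(names(orientation)) == sort(comp)) &&
                all(orientation %in% c(-1, 1)),
              "orientation must assign +1/-1 to each of tsefs, vp, mpod, st")
  assert_that(!anyNA(eye[comp]), "missing eye-index values")
  z <- c("tsefs", "vp", "mpod")
  center <- vapply(eye[z], mean, numeric(1))
  scale <- vapply(eye[z], sd, numeric(1))
  assert_that(all(scale > 0), "zero SD in a z-scored component")
  st_min <- min(eye$st)
  st_max <- max(eye$st)
  assert_that(st_max > st_min, "degenerate Schirmer-test range")
  structure(list(center = center, scale = scale,
                 st_min = st_min, st_max = st_max,
                 orientation = orientation[comp],
                 fit_visit = "v1", sd_convention = "sample (n-1)"),
            class = "vhs_transform")
}

#' @export
print.vhs_transform <- function(x, ...) {
  cat("<vhs_transform> fit on", x$fit_visit, "|",
      "z:", paste(names(x$center), collapse = "/"),
      "| ST min-max: [", x$st_min, ",", x$st_max, "]\n")
  cat("  orientation:", paste(names(x$orientation), x$orientation,
                              sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Aggregate eye indexes into the visual health score
#'
#' Applies frozen transform parameters to the four components and averages the
#' oriented results: `VHS = mean(o_i * t_i)`. Follow-up Schirmer values
#' outside the baseline range extrapolate linearly (the scaled value may leave
#' `[0, 1]`).
#'
#' @param eye Data frame with columns `tsefs`, `vp`, `mpod`, `st`; any other
#'   columns (ids, visit labels) are passed through.
#' @param params A [fit_vhs_transforms()] object.
#' @return The input tibble plus oriented transformed components
#'   (`tsefs_t`, `vp_t`, `mpod_t`, `st_t`) and `vhs`.
#' @export
aggregate_vhs <- function(eye, params) {
  assert_that(inherits(params, "vhs_transform"), "params must be a vhs_transform")
  comp <- c("tsefs", "vp", "mpod", "st")
  assert_that(all(comp %in% names(eye)), "eye table needs tsefs, vp, mpod, st")
  assert_that(!anyNA(eye[comp]), "missing component value")
  out <- as_tibble(eye)
  o <- params$orientation
  for (z in c("tsefs", "vp", "mpod")) {
    out[[paste0(z, "_t")]] <-
      o[[z]] * (out[[z]] - params$center[[z]]) / params$scale[[z]]
  }
  out$st_t <- o[["st"]] * (out$st - params$st_min) / (params$st_max - params$st_min)
  out$vhs <- (out$tsefs_t + out$vp_t + out$mpod_t + out$st_t) / 4
  out
}

#' Score a cohort's visual health at every visit
#'
#' Fits the component transforms on baseline (V1) values pooled across arms
#' (unless `params` is supplied) and applies them at all visits.
#'
#' @param cohort Subject table with per-visit eye columns `tsefs_v1` ...
#'   `st_v3` (visits found by suffix).
#' @param params Optional frozen [fit_vhs_transforms()]; fit on V1 when `NULL`.
#' @param orientation Passed to [fit_vhs_transforms()] when fitting.
#' @return A tibble of class `vhs_scores` with `subject_id`, `visit`,
#'   transformed components and `vhs`; the transform is attached as attribute
#'   `"params"`.
#' @export
score_vhs <- function(cohort, params = NULL,
                      orientation = c(tsefs = -1, vp = 1, mpod = 1, st = 1)) {
  visits <- sort(unique(sub("^tsefs_", "",
                            grep("^tsefs_v", names(cohort), value = TRUE))))
  assert_that(length(visits) >= 1, "no per-visit eye columns found")
  long <- purrr::map_dfr(visits, function(v) {
    tibble(subject_id = cohort$subject_id, visit = v,
           tsefs = cohort[[paste0("tsefs_", v)]],
           vp = cohort[[paste0("vp_", v)]],
           mpod = cohort[[paste0("mpod_", v)]],
           st = cohort[[paste0("st_", v)]])
  })
  if (is.null(params)) {
    params <- fit_vhs_transforms(long[long$visit == "v1", ], orientation)
  }
  out <- aggregate_vhs(long, params)
  attr(out, "params") <- params
  class(out) <- c("vhs_scores", class(out))
  out
}

#' Kolmogorov-Smirnov check of VHS normality
#'
#' One-sample KS test of the score sample against a normal distribution with
#' the sample's own mean and SD (the plain KS statistic; parameters are not
#' re-estimated under the null as a Lilliefors correction would).
#'
#' @param vhs Numeric vector of scores (at least 20 values).
#' @return One-row tibble: `statistic`, `p_value`, `mean`, `sd`, `n`.
#' @export
ks_normality <- function(vhs) {
  vhs <- vhs[!is.na(vhs)]
  assert_that(length(vhs) >= 20, "need at least 20 values for the KS check")
  m <- mean(vhs)
  s <- sd(vhs)
  assert_that(s > 0, "constant sample: KS test against a normal is undefined")
  kt <- suppressWarnings(ks.test(vhs, "pnorm", mean = m, sd = s))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
         mean = m, sd = s, n = length(vhs))
}
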