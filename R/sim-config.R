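#' Simulation configuration for a synthetic 4-arm eye-fatigue RCT
#'
#' Defines the study conditions the cohort generator emulates: a placebo arm
#' plus three lutein doses (6/10/14 mg daily), 303 analyzable subjects, and a
#' ~504-feature baseline panel (demographics, anthropometrics, eye indexes,
#' blood biomarkers, OCT retinal thickness, dietary/FFQ items). Arm-dependent
#' improvement in the composite visual health score (VHS) at the 45-day visit
#' is planted together with a small set of informative baseline features, so
#' downstream feature screening and dose recommendation can be checked against
#' known ground truth.
#'
#' Baseline eye-index moments default to published trial-level values
#' (TSEFS 7.6 +/- 3.6 points, VP 99.5 +/- 15.7 s, MPOD 0.50 +/- 0.17,
#' Schirmer test 7.6 +/- 6.9 mm). `noise_sd` and `responsiveness_sd` default
#' to values giving an oracle prediction ceiling sqrt(R^2) of about 0.67 for
#' VHS at the second visit, a realistic regime for this kind of composite
#' clinical outcome.
#'
#' @param n_subjects Number of analyzable subjects (default 303).
#' @param doses Candidate doses in mg; 0 denotes placebo. One arm per dose.
#' @param n_features_per_group Named counts of generated baseline features for
#'   groups `demographic`, `anthropometric`, `blood`, `oct`, `dietary`. With
#'   the defaults the full feature pool (incl. the four baseline eye indexes,
#'   the appended baseline VHS and the dose feature) is 504.
#' @param dietary_mix How the dietary count splits into continuous intake
#'   scores, discrete frequency items, and multi-choice FFQ items.
#' @param effect_sizes Named coefficients (VHS units per SD) of informative
#'   baseline features on the VHS change at visit 2. Names must be continuous
#'   features of the generated schema.
#' @param dose_response Named per-dose mean VHS change at visit 2 (VHS units);
#'   names are the dose values in mg. Nondecreasing in dose by default.
#' @param noise_sd Residual SD of the VHS change (VHS units).
#' @param responsiveness_sd SD of a per-subject latent responsiveness added to
#'   the VHS change under every dose.
#' @param missing_rate,error_rate Fractions of maskable baseline cells set
#'   missing / replaced by out-of-range "writing mistakes".
#' @param orientation Component orientation signs for VHS (+1 higher-is-better,
#'   -1 flips); see [fit_vhs_transforms()].
#' @param baseline_eye Named list of `c(mean, sd)` for the baseline eye
#'   indexes `tsefs`, `vp`, `mpod`, `st`.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 303,
                       doses = c(0, 6, 10, 14),
                       n_features_per_group = c(demographic = 6,
                                                anthropometric = 10,
                                                blood = 57,
                                                oct = 34,
                                                dietary = 391),
                       dietary_mix = c(continuous = 200,
                                       discrete = 150,
                                       multi_choice = 41),
                       effect_sizes = c(age = -0.15,
                                        anthro_body_fat_rate = -0.12,
                                        blood_hdl = 0.12,
                                        diet_intake_001 = 0.10,
                                        diet_intake_002 = 0.18),
                       dose_response = c(`0` = 0.02, `6` = 0.28,
                                         `10` = 0.38, `14` = 0.50),
                       noise_sd = 0.57,
                       responsiveness_sd = 0.15,
                       missing_rate = 0.02,
                       error_rate = 0.005,
                       orientation = c(tsefs = -1, vp = 1, mpod = 1, st = 1),
                       baseline_eye = list(tsefs = c(7.6, 3.6),
                                           vp = c(99.5, 15.7),
                                           mpod = c(0.50, 0.17),
                                           st = c(7.6, 6.9)),
                       seed = 1L) {
  assert_that(is_scalar_number(n_subjects) && n_subjects >= length(doses),
              "n_subjects must be at least the number of arms")
  assert_that(length(doses) >= 2 && !anyDuplicated(doses),
              "doses must be distinct; include 0 for placebo")
  assert_that(all(names(dose_response) %in% as.character(doses)) &&
                all(as.character(doses) %in% names(dose_response)),
              "dose_response must be named by the dose values")
  dr <- dose_response[as.character(sort(doses))]
  assert_that(!is.unsorted(dr),
              "dose_response should be nondecreasing in dose")
  for (r in c(missing_rate, error_rate))
    assert_that(is_scalar_number(r) && r >= 0 && r <= 1,
                "rates must lie in [0, 1]")
  assert_that(noise_sd >= 0 && responsiveness_sd >= 0,
              "noise SDs must be nonnegative")
  assert_that(sum(dietary_mix) == n_features_per_group[["dietary"]],
              "dietary_mix must sum to the dietary group count")
  cfg <- list(
    n_subjects = as.integer(n_subjects), doses = sort(doses),
    n_features_per_group = n_features_per_group, dietary_mix = dietary_mix,
    effect_sizes = effect_sizes, dose_response = dose_response,
    noise_sd = noise_sd, responsiveness_sd = responsiveness_sd,
    missing_rate = missing_rate, error_rate = error_rate,
    orientation = orientation, baseline_eye = baseline_eye,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> n =", x$n_subjects, "| arms:",
      paste(x$doses, "mg", collapse = ", "), "\n")
  cat("  features/group:",
      paste(names(x$n_features_per_group), x$n_features_per_group,
            sep = "=", collapse = " "), "\n")
  cat("  informative:", length(x$effect_sizes),
      "| noise_sd:", x$noise_sd, "\n")
  invisible(x)
}

arm_label <- function(dose) ifelse(dose == 0, "placebo", paste0(dose, "mg"))

# generic continuous feature rows used to resize groups beyond the canonical set
generic_cont <- function(names, group, mean, sd, lo, hi) {
  tibble(name = names, kind = "continuous", group = group,
         min = lo, max = hi, options = list(NULL),
         probs = list(NULL), dist = "normal", p1 = mean, p2 = sd)
}

#' Build the feature schema implied by a simulation configuration
#'
#' The schema covers every generated baseline column: canonical named features
#' first (age, gender, weight, HDL, ...), generic numbered features filling
#' each group to its configured count. Valid ranges are wide (roughly
#' mean +/- 6-8 SD) so that only injected corruption, never an honest draw,
#' violates them.
#'
#' @param config A [sim_config()].
#' @return A [feature_schema()] (without the derived baseline-VHS feature,
#'   which the pipeline appends after scoring).
#' @export
build_sim_schema <- function(config) {
  npg <- config$n_features_per_group

  demo <- bind_rows(
    generic_cont("age", "demographic", 38.2, 8.3, 18, 90),
    tibble(name = "gender", kind = "discrete", group = "demographic",
           min = NA_real_, max = NA_real_,
           options = list(c("female", "male")),
           probs = list(c(0.779, 0.221)), dist = "categorical",
           p1 = NA_real_, p2 = NA_real_),
    tibble(name = "education", kind = "discrete", group = "demographic",
           min = NA_real_, max = NA_real_,
           options = list(c("primary", "secondary", "tertiary", "postgraduate")),
           probs = list(NULL), dist = "categorical",
           p1 = NA_real_, p2 = NA_real_),
    tibble(name = "income", kind = "discrete", group = "demographic",
           min = NA_real_, max = NA_real_,
           options = list(c("low", "middle", "high")),
           probs = list(NULL), dist = "categorical",
           p1 = NA_real_, p2 = NA_real_),
    generic_cont("sleep_hours", "demographic", 7, 1, 0, 16),
    generic_cont("screen_time_hours", "demographic", 8, 2.5, 0, 24)
  )
  demo <- resize_group(demo, npg[["demographic"]], "demographic",
                       prefix = "demo_var", mean = 50, sd = 10)

  anthro <- bind_rows(
    generic_cont("anthro_weight_kg", "anthropometric", 66.1, 14.2, 30, 200),
    generic_cont("anthro_height_cm", "anthropometric", 164.9, 8.1, 100, 250),
    generic_cont("anthro_body_fat_rate", "anthropometric", 47.5, 11.1, 5, 80),
    generic_cont("anthro_bmi", "anthropometric", 24.3, 3.8, 10, 60),
    generic_cont("anthro_visceral_fat", "anthropometric", 8, 3, 0, 30),
    generic_cont("anthro_fat_free_mass", "anthropometric", 35, 6, 10, 80),
    generic_cont("anthro_waist_cm", "anthropometric", 80, 10, 40, 200),
    generic_cont("anthro_sbp", "anthropometric", 118, 13, 50, 260),
    generic_cont("anthro_dbp", "anthropometric", 75, 10, 30, 160),
    generic_cont("anthro_heart_rate", "anthropometric", 72, 9, 30, 220)
  )
  anthro <- resize_group(anthro, npg[["anthropometric"]], "anthropometric",
                         prefix = "anthro_var", mean = 50, sd = 10)

  blood_named <- bind_rows(
    generic_cont("blood_hdl", "blood", 1.45, 0.35, 0.1, 6),
    generic_cont("blood_ldl", "blood", 2.9, 0.8, 0.1, 12),
    generic_cont("blood_tg", "blood", 1.4, 0.9, 0.05, 15),
    generic_cont("blood_total_chol", "blood", 4.8, 0.9, 1, 15),
    generic_cont("blood_glucose", "blood", 5.2, 0.7, 1, 25),
    generic_cont("blood_creatinine", "blood", 70, 14, 20, 400),
    generic_cont("blood_alt", "blood", 22, 12, 1, 300),
    generic_cont("blood_ast", "blood", 23, 9, 1, 300),
    generic_cont("blood_wbc", "blood", 6.1, 1.5, 1, 30),
    generic_cont("blood_plt", "blood", 245, 55, 20, 900)
  )
  blood <- resize_group(blood_named, npg[["blood"]], "blood",
                        prefix = "blood_marker", mean = 50, sd = 8)

  oct <- resize_group(tibble(), npg[["oct"]], "oct",
                      prefix = "oct_thickness", mean = 280, sd = 25)

  mix <- config$dietary_mix
  diet_cont <- generic_cont(sprintf("diet_intake_%03d", seq_len(mix[["continuous"]])),
                            "dietary", NA, NA, 0, 5000)
  diet_cont$dist <- "lognormal"
  diet_cont$p1 <- log(30)
  diet_cont$p2 <- 0.6
  diet_disc <- tibble(
    name = sprintf("ffq_item_%03d", seq_len(mix[["discrete"]])),
    kind = "discrete", group = "dietary", min = NA_real_, max = NA_real_,
    options = list(c("never", "sometimes", "often")),
    probs = list(NULL), dist = "categorical", p1 = NA_real_, p2 = NA_real_
  )
  diet_multi <- purrr::map_dfr(seq_len(mix[["multi_choice"]]), function(j) {
    k <- 3L + (j - 1L) %% 6L  # option counts cycle through 3..8
    tibble(name = sprintf("ffq_multi_%03d", j), kind = "multi_choice",
           group = "dietary", min = NA_real_, max = NA_real_,
           options = list(paste0("opt_", letters[seq_len(k)])),
           probs = list(NULL), dist = "multihot", p1 = 0.35, p2 = NA_real_)
  })

  eye <- bind_rows(
    generic_cont("tsefs_v1", "eye",
                 config$baseline_eye$tsefs[1], config$baseline_eye$tsefs[2], 0, 45),
    generic_cont("vp_v1", "eye",
                 config$baseline_eye$vp[1], config$baseline_eye$vp[2], 0, 300),
    generic_cont("mpod_v1", "eye",
                 config$baseline_eye$mpod[1], config$baseline_eye$mpod[2], 0, 1.5),
    generic_cont("st_v1", "eye",
                 config$baseline_eye$st[1], config$baseline_eye$st[2], 0, 35)
  )
  eye$dist[eye$name == "st_v1"] <- "gamma_ms"  # right-skewed, mean/sd parameterised

  dose <- generic_cont("dose", "dose", NA, NA, 0, max(config$doses))
  dose$dist <- "assigned"

  feature_schema(bind_rows(demo, anthro, eye, blood, oct,
                           diet_cont, diet_disc, diet_multi, dose))
}

resize_group <- function(canonical, n, group, prefix, mean, sd) {
  n <- as.integer(n)
  if (nrow(canonical) >= n) return(utils::head(canonical, n))
  extra_n <- n - nrow(canonical)
  j <- seq_len(extra_n)
  extra <- generic_cont(sprintf("%s_%02d", prefix, j + nrow(canonical)), group,
                        mean + 3 * j, sd + 0.2 * j,
                        mean + 3 * j - 8 * (sd + 0.2 * j),
                        mean + 3 * j + 8 * (sd + 0.2 * j))
  bind_rows(canonical, extra)
}
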