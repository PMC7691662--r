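test_that("the three-branch rule reproduces worked examples", {
  # exact indifference: zero spread, improvement clears the bar
  r1 <- recommend_dose(c(`6` = 0.50, `10` = 0.50, `14` = 0.50),
                       baseline_vhs = -0.2)
  expect_equal(as.character(r1$category), "lower_dose_sufficient")
  expect_equal(r1$recommended_dose, 6)

  # clear improvement and spread with the top dose best
  r2 <- recommend_dose(c(`6` = 0.20, `10` = 0.30, `14` = 0.45),
                       baseline_vhs = 0)
  expect_equal(as.character(r2$category), "highest_dose_optimal")
  expect_equal(r2$recommended_dose, 14)

  # high baseline: best improvement 0.05 <= 0.1 means no benefit
  r3 <- recommend_dose(c(`6` = 1.24, `10` = 1.25, `14` = 1.25),
                       baseline_vhs = 1.20)
  expect_equal(as.character(r3$category), "no_benefit")
  expect_true(is.na(r3$recommended_dose))

  # argmax below the top dose with real spread
  r4 <- recommend_dose(c(`6` = 0.10, `10` = 0.40, `14` = 0.30),
                       baseline_vhs = 0)
  expect_equal(as.character(r4$category), "lower_dose_sufficient")
  expect_equal(r4$recommended_dose, 10)

  # single candidate
  r5 <- recommend_dose(c(`10` = 0.5), baseline_vhs = 0)
  expect_equal(r5$recommended_dose, 10)
  expect_error(recommend_dose(numeric(0), 0), "nonempty")
})

test_that("rule matches branch enumeration on a coarse lattice", {
  vals <- seq(-0.2, 0.6, by = 0.05)
  grid <- expand.grid(p6 = vals, p10 = vals, p14 = vals)
  pred <- as.matrix(grid)
  colnames(pred) <- c("6", "10", "14")
  for (base in c(-0.5, 0, 0.5)) {
    got <- lutidose:::categorize_doses(pred, base)
    # independent scalar enumeration of the branches
    exp_cat <- apply(pred, 1, function(p) {
      if (max(p) - base <= 0.1) return("no_benefit")
      if (max(p) - min(p) < 0.05) return("lower_dose_sufficient")
      am <- c(6, 10, 14)[which.max(p)]
      if (am == 14) "highest_dose_optimal" else "lower_dose_sufficient"
    })
    expect_identical(as.character(got$category), unname(exp_cat))
  }
})

test_that("categories are invariant to a common shift of predictions and baseline", {
  withr::with_seed(61, {
    pred <- matrix(runif(300 * 3, -0.2, 0.6), 300, 3,
                   dimnames = list(NULL, c("6", "10", "14")))
    base <- runif(300, -0.5, 0.5)
  })
  a <- lutidose:::categorize_doses(pred, base)
  b <- lutidose:::categorize_doses(pred + 0.37, base + 0.37)
  expect_identical(a, b)
})

test_that("counterfactual predictions vary only through the dose entry", {
  withr::with_seed(62, {
    n <- 120
    x <- cbind(vhs_v1 = rnorm(n, 0, 0.5),
               dose = sample(c(0, 6, 10, 14), n, replace = TRUE),
               other = rnorm(n))
    rownames(x) <- sprintf("S%03d", 1:n)
    y <- x[, "vhs_v1"] + 0.03 * x[, "dose"] + rnorm(n, 0, 0.1)
  })
  m <- tune_and_train(x, y, grid = tibble::tibble(max_depth = 2, nrounds = 200),
                      k = 5, seed = 1)
  cf <- counterfactual_predictions(m, x, doses = c(6, 10, 14))
  expect_equal(nrow(cf), n * 3)
  expect_setequal(unique(cf$dose), c(6, 10, 14))

  # a dose-blind model returns identical predictions at every dose
  x_blind <- x
  x_blind[, "dose"] <- 7 # constant in training: never used for a split
  mb <- tune_and_train(x_blind, y, grid = tibble::tibble(max_depth = 2,
                                                         nrounds = 100),
                       k = 5, seed = 1)
  cfb <- counterfactual_predictions(mb, x_blind, doses = c(6, 10, 14))
  wide <- tidyr::pivot_wider(cfb, names_from = "dose",
                             values_from = "predicted_vhs")
  expect_equal(wide$`6`, wide$`10`)
  expect_equal(wide$`10`, wide$`14`)

  # single candidate gives a map of size one per subject
  one <- counterfactual_predictions(m, x[1:3, ], doses = 10)
  expect_equal(nrow(one), 3)

  m_nodose <- tune_and_train(x[, c("vhs_v1", "other")], y,
                             grid = tibble::tibble(max_depth = 2, nrounds = 50),
                             k = 5, seed = 1)
  expect_error(counterfactual_predictions(m_nodose, x), "dose feature")
})

test_that("noiseless monotone dose response yields nondecreasing predictions", {
  cfg <- small_config(noise_sd = 0, responsiveness_sd = 0,
                      effect_sizes = setNames(numeric(0), character(0)),
                      missing_rate = 0, error_rate = 0, n_subjects = 120)
  sim <- generate_cohort(cfg, seed = 7)
  sc <- score_vhs(sim$cohort)
  v1 <- sc[sc$visit == "v1", ]
  v2 <- sc[sc$visit == "v2", ]
  x <- cbind(vhs_v1 = v1$vhs, dose = sim$cohort$dose)
  rownames(x) <- sim$cohort$subject_id
  m <- tune_and_train(x, v2$vhs, grid = tibble::tibble(max_depth = 2,
                                                       nrounds = 300),
                      k = 5, seed = 7)
  cf <- counterfactual_predictions(m, x, doses = c(6, 10, 14))
  wide <- tidyr::pivot_wider(cf, names_from = "dose",
                             values_from = "predicted_vhs")
  expect_true(all(wide$`10` >= wide$`6` - 1e-9))
  expect_true(all(wide$`14` >= wide$`10` - 1e-9))

  # dose response exceeds both thresholds, so every subject with the planted
  # monotone benefit is categorised at the highest dose
  recs <- recommend_doses(m, x, setNames(v1$vhs, v1$subject_id))
  expect_true(all(recs$category == "highest_dose_optimal"))
})

test_that("summaries report category counts with one-decimal percentages", {
  recs <- tibble::tibble(
    category = factor(rep(c("highest_dose_optimal", "lower_dose_sufficient",
                            "no_benefit"), c(39, 17, 2)),
                      levels = c("no_benefit", "lower_dose_sufficient",
                                 "highest_dose_optimal")))
  class(recs) <- c("dose_recommendations", class(recs))
  s <- summarize_recommendations(recs)
  got <- setNames(s$pct, s$category)
  expect_equal(got[["highest_dose_optimal"]], 67.2)
  expect_equal(got[["lower_dose_sufficient"]], 29.3)
  expect_equal(got[["no_benefit"]], 3.4)
  expect_lte(abs(sum(s$pct) - 100), 0.1)

  one <- recs[1, ]
  class(one) <- c("dose_recommendations", class(recs))
  expect_equal(summarize_recommendations(one)$pct[3], 100)
})
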