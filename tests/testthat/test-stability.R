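test_that("a feature that determines the response is always selected", {
  withr::with_seed(51, {
    n <- 60
    x <- cbind(x1 = rnorm(n),
               matrix(rnorm(n * 20), n, 20,
                      dimnames = list(NULL, paste0("noise", 1:20))))
    rownames(x) <- sprintf("S%03d", 1:n)
  })
  y <- as.numeric(x[, "x1"]) # y identically equal to x1
  res <- stability_scores(x, y, stability_config(depths = c(2, 5),
                                                 n_subsamples = 20, seed = 1))
  expect_equal(res$scores$score[res$scores$feature == "x1"], 1)

  solo <- stability_scores(x[, "x1", drop = FALSE], y,
                           stability_config(depths = 2, n_subsamples = 10,
                                            seed = 1))
  expect_equal(solo$scores$score, 1) # the only candidate
})

test_that("selection respects the threshold, order and forced-in features", {
  res <- structure(list(
    scores = tibble::tibble(feature = c("a", "b", "c"), group = "blood",
                            score = c(0.9, 0.8, 0.3)),
    force_in = character(0)), class = "stability_result")
  expect_equal(select_features(res, 0.8), c("a", "b"))
  expect_equal(select_features(res, 0), c("a", "b", "c"))
  expect_true(length(select_features(res, 1)) < 3) # strict subset
  res$force_in <- "c"
  expect_equal(select_features(res, 0.95), "c")
  expect_error(select_features(res, 1.2), "threshold")
})

test_that("selected sets are nonincreasing in the threshold", {
  withr::with_seed(52, {
    n <- 80
    x <- matrix(rnorm(n * 15), n, 15, dimnames = list(NULL, paste0("f", 1:15)))
    y <- x[, 1] + 0.5 * x[, 2] + rnorm(n)
  })
  res <- stability_scores(x, y, stability_config(depths = 2:4,
                                                 n_subsamples = 25, seed = 2))
  sizes <- vapply(seq(0, 1, by = 0.05),
                  function(t) length(select_features(res, t)), integer(1))
  expect_true(all(diff(sizes) <= 0))
  sel_lo <- select_features(res, 0.3)
  sel_hi <- select_features(res, 0.7)
  expect_true(all(sel_hi %in% sel_lo))
})

test_that("scores are invariant to subject order (membership drawn by id)", {
  withr::with_seed(53, {
    n <- 40
    x <- matrix(rnorm(n * 8), n, 8,
                dimnames = list(sprintf("S%03d", 1:n), paste0("f", 1:8)))
    y <- setNames(x[, 1] - x[, 2] + rnorm(n, 0, 0.5), rownames(x))
    perm <- sample(n)
  })
  cfg <- stability_config(depths = 2:3, n_subsamples = 20, seed = 4)
  a <- stability_scores(x, unname(y), cfg)
  b <- stability_scores(x[perm, ], unname(y[perm]), cfg)
  expect_identical(a$scores, b$scores)
})

test_that("exhaustive half-subset frequencies match an independent enumeration", {
  withr::with_seed(54, {
    n <- 8
    x <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(sprintf("S%d", 1:n), paste0("f", 1:4)))
    y <- x[, 1] + 0.8 * x[, 2] + rnorm(n, 0, 0.5)
  })
  cfg <- stability_config(depths = 1, learner = "stump",
                          subsample_mode = "exhaustive", seed = 1)
  res <- stability_scores(x, y, cfg)

  # independent oracle: enumerate all half-subsets, refit a best-SSE stump
  oracle_stump_feature <- function(xs, ys) {
    best_sse <- sum((ys - mean(ys))^2)
    best_feat <- NULL
    for (j in seq_len(ncol(xs))) {
      v <- sort(unique(xs[, j]))
      if (length(v) < 2) next
      for (t in (v[-length(v)] + v[-1]) / 2) {
        l <- xs[, j] <= t
        sse <- sum((ys[l] - mean(ys[l]))^2) + sum((ys[!l] - mean(ys[!l]))^2)
        if (sse < best_sse - 1e-12) {
          best_sse <- sse
          best_feat <- colnames(xs)[j]
        }
      }
    }
    best_feat
  }
  ids <- sort(rownames(x))
  subsets <- combn(ids, 4, simplify = FALSE)
  counts <- setNames(numeric(4), colnames(x))
  for (s in subsets) {
    f <- oracle_stump_feature(x[s, , drop = FALSE], y[match(s, rownames(x))])
    if (!is.null(f)) counts[f] <- counts[f] + 1
  }
  expect_equal(length(subsets), choose(8, 4))
  got <- setNames(res$scores$score, res$scores$feature)
  expect_identical(got[colnames(x)], counts / length(subsets))
})

test_that("threshold choice follows the fewest-features-within-tolerance rule", {
  d <- planted_design(n = 150, p = 12, k = 2, r2 = 0.6, seed = 5)
  cfg <- stability_config(depths = 2:4, n_subsamples = 30, seed = 5)
  res <- stability_scores(d$x, d$y, cfg)

  # infinite tolerance: criterion 2 is vacuous, largest nonempty candidate wins
  inf_res <- choose_threshold(d$x, d$y, res, candidates = c(0.2, 0.5, 0.8),
                              k = 5, tolerance = Inf, seed = 5)
  nonempty <- Filter(function(t) length(select_features(res, t)) > 0,
                     c(0.2, 0.5, 0.8))
  expect_equal(inf_res$chosen_threshold, max(nonempty))

  # a single candidate that matches baseline PCC is chosen
  one <- choose_threshold(d$x, d$y, res, candidates = 0.5, k = 5,
                          tolerance = Inf, seed = 5)
  expect_equal(one$chosen_threshold, 0.5)
  expect_equal(one$selected, select_features(res, 0.5))
  expect_equal(nrow(one$sweep), 1)

  # impossible criterion: threshold falls back to 0 with a warning
  expect_warning(
    zero <- choose_threshold(d$x, d$y, res, candidates = 0.99, k = 5,
                             tolerance = -2, seed = 5),
    "no candidate")
  expect_equal(zero$chosen_threshold, 0)
})

test_that("tidy and glance expose scores and the sweep summary", {
  d <- planted_design(n = 100, p = 8, k = 1, r2 = 0.6, seed = 6)
  res <- stability_scores(d$x, d$y,
                          stability_config(depths = 2, n_subsamples = 15,
                                           seed = 6))
  res <- choose_threshold(d$x, d$y, res, candidates = c(0.5, 0.8), k = 5,
                          tolerance = Inf, seed = 6)
  td <- tidy(res)
  expect_true(all(c("feature", "score", "selected") %in% names(td)))
  expect_true(!is.unsorted(rev(td$score)))
  gl <- glance(res)
  expect_equal(gl$n_features, 8)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})
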