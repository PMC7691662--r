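#' @importFrom ggplot2 ggplot aes geom_col geom_line geom_point geom_hline
#'   geom_histogram labs autoplot scale_y_continuous sec_axis after_stat
#'   stat_function theme_minimal
NULL

#' Threshold-sweep plot for a stability-selection result
#'
#' Feature count (bars) and 10-fold CV PCC (line) per candidate threshold,
#' the all-features baseline PCC as a dashed line, and a marker at the chosen
#' threshold.
#'
#' @param object A [choose_threshold()]-updated `stability_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_result <- function(object, ...) {
  assert_that(!is.null(object$sweep),
              "run choose_threshold() before plotting the sweep")
  sw <- object$sweep
  scale_f <- max(sw$n_features) / max(abs(sw$cv_pcc), na.rm = TRUE)
  ggplot(sw, aes(x = .data$threshold)) +
    geom_col(aes(y = .data$n_features), fill = "steelblue", alpha = 0.5,
             width = 0.03) +
    geom_line(aes(y = .data$cv_pcc * scale_f), color = "blue") +
    geom_hline(yintercept = object$baseline_cv_pcc * scale_f,
               linetype = "dashed", color = "grey40") +
    geom_point(data = sw[sw$threshold == object$chosen_threshold, ],
               aes(y = .data$cv_pcc * scale_f), shape = 8, size = 3,
               color = "red") +
    scale_y_continuous("selected features",
                       sec.axis = sec_axis(~ . / scale_f, name = "10xCV PCC")) +
    labs(x = "stability-score threshold",
         title = "Stability selection threshold sweep") +
    theme_minimal()
}

#' Category plot for dose recommendations
#'
#' @param object A [recommend_doses()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dose_recommendations <- function(object, ...) {
  summ <- summarize_recommendations(object)
  ggplot(summ, aes(x = .data$category, y = .data$n)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "subjects",
         title = "Recommended-dose categories") +
    theme_minimal()
}

#' Histogram of the composite score with its fitted normal curve
#'
#' @param scores A [score_vhs()] tibble (or any data frame with a `vhs`
#'   column); by default the baseline visit is shown.
#' @param visit Visit label to plot (`NULL` = all rows).
#' @return A ggplot object.
#' @export
plot_vhs_distribution <- function(scores, visit = "v1") {
  df <- as_tibble(scores)
  if (!is.null(visit) && "visit" %in% names(df)) df <- df[df$visit == visit, ]
  m <- mean(df$vhs)
  s <- sd(df$vhs)
  ggplot(df, aes(x = .data$vhs)) +
    geom_histogram(aes(y = after_stat(.data$density)), bins = 30,
                   fill = "steelblue", alpha = 0.6) +
    stat_function(fun = stats::dnorm, args = list(mean = m, sd = s),
                  color = "red") +
    labs(x = "VHS", y = "density",
         title = sprintf("VHS distribution (mean %.3f, SD %.3f)", m, s)) +
    theme_minimal()
}
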