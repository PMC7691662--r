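#' @importFrom rlang %||% abort warn
#' @importFrom dplyr mutate filter select arrange bind_rows bind_cols group_by
#'   summarise ungroup left_join pull n across all_of row_number
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_chr map_int map2 pmap imap keep
#' @importFrom stats rnorm rlnorm runif rbinom sd var cor predict quantile
#'   ks.test setNames
#' @importFrom utils head combn
NULL

# deterministic stream splitting: keeps derived seeds positive 32-bit ints
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.double(seed) * 48271 + as.double(offset) * 9973) %% 2147483629 + 1)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# column mode for categorical imputation; ties broken toward first-sorted level
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_character_)
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1L]
}

# multi-choice cells travel as ";"-separated option strings; "" is the empty set
split_multi <- function(x) {
  if (is.na(x) || identical(x, "")) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}

join_multi <- function(opts) paste(opts, collapse = ";")
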