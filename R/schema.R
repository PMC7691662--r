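#' Feature schema
#'
#' A feature schema declares, for every baseline feature, its name, kind
#' (`continuous`, `discrete`, `multi_choice`), feature group (`demographic`,
#' `anthropometric`, `eye`, `blood`, `oct`, `dietary`, `dose`), and either a
#' valid numeric range (continuous) or the list of admissible options
#' (discrete / multi-choice). The schema drives cleaning ("obvious writing
#' mistakes" are operationalised as range/option violations), encoding
#' (one-hot for discrete, multi-hot for multi-choice), and group ablations.
#'
#' @param features A data frame with columns `name`, `kind`, `group`, and
#'   either `min`/`max` (continuous) or a list-column `options`
#'   (discrete / multi-choice). Extra columns are preserved.
#' @return A tibble of class `feature_schema`.
#' @export
feature_schema <- function(features) {
  sch <- as_tibble(features)
  required <- c("name", "kind", "group")
  assert_that(all(required %in% names(sch)),
              "schema needs columns name, kind, group")
  if (!"min" %in% names(sch)) sch$min <- NA_real_
  if (!"max" %in% names(sch)) sch$max <- NA_real_
  if (!"options" %in% names(sch)) sch$options <- vector("list", nrow(sch))
  assert_that(!anyDuplicated(sch$name), "feature names must be unique")
  assert_that(all(sch$kind %in% c("continuous", "discrete", "multi_choice")),
              "kind must be continuous, discrete or multi_choice")
  cont <- sch$kind == "continuous"
  assert_that(all(is.finite(sch$min[cont]) & is.finite(sch$max[cont]) &
                    sch$min[cont] < sch$max[cont]),
              "every continuous feature needs a finite valid range min < max")
  cat_ok <- vapply(sch$options[!cont], function(o) length(o) >= 2L, logical(1))
  assert_that(all(cat_ok),
              "every discrete/multi_choice feature needs >= 2 declared options")
  class(sch) <- c("feature_schema", class(sch))
  sch
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema> ", nrow(x), " features\n", sep = "")
  print(dplyr::count(as_tibble(x), .data$group, .data$kind), ...)
  invisible(x)
}

schema_features <- function(schema, groups = NULL, kinds = NULL) {
  keep <- rep(TRUE, nrow(schema))
  if (!is.null(groups)) keep <- keep & schema$group %in% groups
  if (!is.null(kinds)) keep <- keep & schema$kind %in% kinds
  schema$name[keep]
}

#' Write / read a feature schema as JSON
#'
#' @param schema A [feature_schema()].
#' @param path File path.
#' @return `write_schema_json()` returns `path` invisibly; `read_schema_json()`
#'   returns the schema.
#' @export
write_schema_json <- function(schema, path) {
  recs <- purrr::pmap(schema, function(name, kind, group, min, max, options, ...) {
    extra <- list(...)
    rec <- list(name = name, kind = kind, group = group)
    if (kind == "continuous") rec$range <- c(min, max) else rec$options <- options
    gen <- extra[intersect(names(extra), c("dist", "p1", "p2"))]
    gen <- gen[!vapply(gen, function(v) length(v) != 1 || is.na(v), logical(1))]
    if (length(gen)) rec$generator <- gen
    rec
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_schema_json
#' @export
read_schema_json <- function(path) {
  recs <- jsonlite::read_json(path)
  rows <- purrr::map(recs, function(r) {
    tibble(
      name = r$name, kind = r$kind, group = r$group,
      min = if (!is.null(r$range)) as.numeric(r$range[[1]]) else NA_real_,
      max = if (!is.null(r$range)) as.numeric(r$range[[2]]) else NA_real_,
      options = list(as.character(unlist(r$options))),
      dist = r$generator$dist %||% NA_character_,
      p1 = r$generator$p1 %||% NA_real_,
      p2 = r$generator$p2 %||% NA_real_
    )
  })
  feature_schema(bind_rows(rows))
}
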