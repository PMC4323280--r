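#' Instrument schemas
#'
#' An instrument schema is a declarative description of a standardized
#' questionnaire: its ordered item identifiers, the common per-item response
#' bounds, which items are reverse coded, and a named partition of the items
#' into subscales. Scoring is always "sum over items after reverse coding"
#' with complete-case missing handling, which covers every instrument in the
#' validation battery (PSS-4/PSS-14, ESI, HSCL-25, SCL-90-R somatization,
#' PDS parts 1 and 3, CFV).
#'
#' @param instrument_id Single string naming the instrument.
#' @param items Character vector of item ids, in instrument order.
#' @param response_min,response_max Integer per-item response bounds
#'   (e.g. 0--4 for the PSS, 1--4 for the HSCL-25).
#' @param reverse_coded Character vector, a subset of `items`, of items to
#'   reflect before summation.
#' @param subscales Named list of character vectors partitioning `items`.
#'   Defaults to a single subscale `total` containing all items.
#' @param version Schema version string.
#' @param label Human-readable instrument name.
#' @param notes Free-text caveats carried with the schema.
#'
#' @return An object of class `instrument_schema`.
#' @export
instrument_schema <- function(instrument_id, items, response_min, response_max,
                              reverse_coded = character(),
                              subscales = list(total = items),
                              version = "1.0", label = instrument_id,
                              notes = NULL) {
  stopifnot(is.character(instrument_id), length(instrument_id) == 1L,
            is.character(items), length(items) >= 1L)
  response_min <- as.integer(response_min)
  response_max <- as.integer(response_max)
  if (anyDuplicated(items)) {
    stop("duplicate item ids in schema '", instrument_id, "'", call. = FALSE)
  }
  if (!(response_min < response_max)) {
    stop("response_min must be strictly below response_max", call. = FALSE)
  }
  if (!all(reverse_coded %in% items)) {
    bad <- setdiff(reverse_coded, items)
    stop("reverse_coded items not in item list: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  flat <- unlist(subscales, use.names = FALSE)
  if (anyDuplicated(flat) || !setequal(flat, items)) {
    stop("subscales must partition the item list (pairwise disjoint, union = items)",
         call. = FALSE)
  }
  structure(
    list(instrument_id = instrument_id, version = version, label = label,
         items = items, response_min = response_min,
         response_max = response_max,
         reverse_coded = as.character(reverse_coded),
         subscales = lapply(subscales, as.character),
         scoring_rule = "sum over items after reverse coding",
         missing_policy = "complete_case", notes = notes),
    class = "instrument_schema"
  )
}

#' @export
print.instrument_schema <- function(x, ...) {
  cat("<instrument_schema> ", x$instrument_id, " (v", x$version, ")\n", sep = "")
  cat("  ", x$label, "\n", sep = "")
  cat("  items: ", length(x$items), ", response range ", x$response_min, "-",
      x$response_max, ", ", length(x$reverse_coded), " reverse coded\n",
      sep = "")
  cat("  subscales: ",
      paste(sprintf("%s (%d)", names(x$subscales), lengths(x$subscales)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Load an instrument schema from a JSON document
#'
#' Schemas ship with the package as versioned JSON files, one per instrument;
#' user-supplied files in the same layout (for translations or editions with
#' different item sets) are read the same way.
#'
#' @param path Path to a schema JSON file.
#' @return An `instrument_schema`.
#' @export
read_schema <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("instrument_id", "items", "response_min", "response_max")
  missing <- setdiff(required, names(doc))
  if (length(missing)) {
    stop("schema document ", path, " lacks fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  instrument_schema(
    instrument_id = doc$instrument_id,
    items = doc$items,
    response_min = doc$response_min,
    response_max = doc$response_max,
    reverse_coded = if (is.null(doc$reverse_coded)) character() else doc$reverse_coded,
    subscales = if (is.null(doc$subscales)) list(total = doc$items) else doc$subscales,
    version = if (is.null(doc$version)) "1.0" else doc$version,
    label = if (is.null(doc$label)) doc$instrument_id else doc$label,
    notes = doc$notes
  )
}

#' Built-in validation-battery schemas
#'
#' @param instrument_id One of `"pss14"`, `"pss4"`, `"esi"`, `"hscl25"`,
#'   `"scl90r_somatization"`, `"pds_events"`, `"pds_symptoms"`, `"cfv"`.
#'   With no argument, returns the named list of all built-in schemas.
#' @return An `instrument_schema`, or a named list of them.
#' @export
#' @examples
#' score_range(kindex_schemas("pss14"))
kindex_schemas <- function(instrument_id = NULL) {
  dir <- system.file("extdata", "schemas", package = "kindexr")
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  all <- lapply(files, read_schema)
  names(all) <- vapply(all, `[[`, character(1), "instrument_id")
  if (is.null(instrument_id)) return(all)
  if (!instrument_id %in% names(all)) {
    stop("unknown built-in instrument '", instrument_id, "'; available: ",
         paste(names(all), collapse = ", "), call. = FALSE)
  }
  all[[instrument_id]]
}
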