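#' @keywords internal
#' @noRd
schema_item_matrix <- function(schema, responses, check_bounds = TRUE) {
  if (!"respondent_id" %in% names(responses)) {
    stop("responses must have a respondent_id column", call. = FALSE)
  }
  unknown <- setdiff(setdiff(names(responses), "respondent_id"), schema$items)
  if (length(unknown)) {
    stop("unknown item columns for instrument '", schema$instrument_id, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(schema$items, names(responses))
  if (length(absent)) {
    stop("missing item columns for instrument '", schema$instrument_id, "': ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(responses[schema$items])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(responses$respondent_id)
  if (check_bounds) {
    bad <- which(!is.na(m) & (m < schema$response_min | m > schema$response_max),
                 arr.ind = TRUE)
    if (nrow(bad)) {
      first <- bad[1, , drop = TRUE]
      stop(sprintf(
        "out-of-range value %s for item %s, respondent %s (instrument %s, allowed %d-%d); %d offending value(s) in total",
        format(m[bad[1, 1], bad[1, 2]]), schema$items[first[["col"]]],
        rownames(m)[first[["row"]]], schema$instrument_id,
        schema$response_min, schema$response_max, nrow(bad)), call. = FALSE)
    }
  }
  m
}

#' Reverse code the reverse-keyed items of a response table
#'
#' Positively worded items are reflected onto the symptom/stress direction
#' before summation: a value `v` on an item with bounds `[lo, hi]` maps to
#' `lo + hi - v`. All other items, and missing values, are unchanged.
#'
#' @param schema An [instrument_schema()].
#' @param responses Wide tibble: `respondent_id` plus one column per schema
#'   item.
#' @return A tibble of the same shape with reverse-keyed items reflected.
#' @export
#' @examples
#' s <- kindex_schemas("pss4")
#' r <- tibble::tibble(respondent_id = "a",
#'                     pss4_1 = 0, pss4_2 = 4, pss4_3 = 2, pss4_4 = 1)
#' reverse_code(s, r)
reverse_code <- function(schema, responses) {
  m <- schema_item_matrix(schema, responses)
  rev_items <- intersect(schema$reverse_coded, colnames(m))
  m[, rev_items] <- schema$response_min + schema$response_max - m[, rev_items]
  out <- responses
  out[schema$items] <- as.data.frame(m, row.names = NULL)
  out
}

#' Score an instrument for a table of respondents
#'
#' Applies reverse coding, then sums items within each subscale and across
#' all items. Missingness follows complete-case handling: a subscale sum is
#' missing when any of its items is missing, the total is missing when any
#' item of the instrument is missing, and `complete` records whether every
#' item was answered.
#'
#' @inheritParams reverse_code
#' @return Tibble with `respondent_id`, one `<subscale>` column per schema
#'   subscale (named `total` when there is a single all-item subscale),
#'   `total`, and logical `complete`.
#' @export
score_instrument <- function(schema, responses) {
  m <- schema_item_matrix(schema, responses)
  rev_items <- intersect(schema$reverse_coded, colnames(m))
  m[, rev_items] <- schema$response_min + schema$response_max - m[, rev_items]
  out <- tibble::tibble(respondent_id = responses$respondent_id)
  for (sub in names(schema$subscales)) {
    cols <- schema$subscales[[sub]]
    out[[sub]] <- unname(rowSums(m[, cols, drop = FALSE]))  # NA if any item missing
  }
  complete <- unname(!apply(is.na(m), 1L, any))
  sub_names <- names(schema$subscales)
  if (identical(sub_names, "total")) {
    out$total <- out[["total"]]
  } else {
    out$total <- rowSums(as.matrix(out[sub_names]))
  }
  out$complete <- complete
  out
}

#' Attainable score bounds of an instrument
#'
#' Analytic minimum and maximum of the total (and each subscale) under the
#' schema's scoring rule. Reflection of reverse-keyed items does not change
#' attainable bounds, so the total ranges over
#' `[n_items * response_min, n_items * response_max]`.
#'
#' @inheritParams reverse_code
#' @return List with `total = c(min, max)` and `subscales`, a named list of
#'   `c(min, max)` per subscale.
#' @export
#' @examples
#' score_range(kindex_schemas("esi"))$total   # 0 60
score_range <- function(schema) {
  rng <- function(k) c(min = k * schema$response_min,
                       max = k * schema$response_max)
  list(total = unname(rng(length(schema$items))),
       subscales = lapply(schema$subscales, function(it) unname(rng(length(it)))))
}

#' Validate a response table against a schema
#'
#' Report-only check: lists out-of-range values, unknown item columns, and
#' per-item missingness counts. The data are never mutated and no error is
#' raised for data problems.
#'
#' @inheritParams reverse_code
#' @return List of class `kindex_validation_report` with `issues` (tibble:
#'   `respondent_id`, `item`, `type`, `value`) and `missing_counts` (tibble:
#'   `item`, `n_missing`).
#' @export
validate_responses <- function(schema, responses) {
  issues <- list()
  unknown <- setdiff(setdiff(names(responses), "respondent_id"), schema$items)
  for (it in unknown) {
    issues[[length(issues) + 1L]] <- tibble::tibble(
      respondent_id = NA_character_, item = it, type = "unknown_item",
      value = NA_real_)
  }
  known <- intersect(schema$items, names(responses))
  m <- as.matrix(responses[known])
  storage.mode(m) <- "double"
  oob <- which(!is.na(m) & (m < schema$response_min | m > schema$response_max),
               arr.ind = TRUE)
  if (length(oob)) {
    issues[[length(issues) + 1L]] <- tibble::tibble(
      respondent_id = as.character(responses$respondent_id)[oob[, 1]],
      item = known[oob[, 2]], type = "out_of_range",
      value = m[oob])
  }
  absent <- setdiff(schema$items, names(responses))
  for (it in absent) {
    issues[[length(issues) + 1L]] <- tibble::tibble(
      respondent_id = NA_character_, item = it, type = "absent_item",
      value = NA_real_)
  }
  issues <- if (length(issues)) dplyr::bind_rows(issues) else
    tibble::tibble(respondent_id = character(), item = character(),
                   type = character(), value = double())
  missing_counts <- tibble::tibble(
    item = known,
    n_missing = unname(colSums(is.na(m))))
  structure(list(instrument_id = schema$instrument_id, issues = issues,
                 missing_counts = missing_counts,
                 n_respondents = nrow(responses)),
            class = "kindex_validation_report")
}

#' @export
print.kindex_validation_report <- function(x, ...) {
  cat("<validation report> ", x$instrument_id, ": ", x$n_respondents,
      " respondents\n", sep = "")
  cat("  issues: ", nrow(x$issues), "\n", sep = "")
  if (nrow(x$issues)) print(x$issues, n = 10)
  n_miss <- sum(x$missing_counts$n_missing)
  cat("  missing values: ", n_miss, "\n", sep = "")
  invisible(x)
}

#' Score the full validation battery
#'
#' Runs [score_instrument()] for every battery table present and assembles
#' the per-respondent criterion totals used by the global composites:
#' PSS-14 total, ESI total, HSCL-25 anxiety/depression/combined totals,
#' SCL-90-R somatization total, PDS event count and symptom severity, and
#' the CFV subscale and overall totals.
#'
#' @param battery Named list of wide response tibbles keyed by instrument id
#'   (as produced by [generate_cohort()] or [read_battery()]).
#' @param schemas Named list of schemas, default the built-in set.
#' @return Tibble with one row per respondent: `respondent_id`,
#'   `pss14_total`, `esi_total`, `hscl_anxiety`, `hscl_depression`,
#'   `hscl_total`, `scl_somatization`, `pds_events`, `pds_severity`,
#'   `cfv_physical`, `cfv_verbal_emotional`, `cfv_sexual`, `cfv_witnessed`,
#'   `cfv_neglect`, `cfv_total`.
#' @export
score_battery <- function(battery, schemas = kindex_schemas()) {
  need <- c("pss14", "esi", "hscl25", "scl90r_somatization",
            "pds_events", "pds_symptoms", "cfv")
  absent <- setdiff(need, names(battery))
  if (length(absent)) {
    stop("battery lacks instrument tables: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  sc <- lapply(need, function(id) score_instrument(schemas[[id]], battery[[id]]))
  names(sc) <- need
  out <- tibble::tibble(respondent_id = sc$pss14$respondent_id)
  pick <- function(id, col, new) {
    s <- sc[[id]]
    out[[new]] <<- s[[col]][match(out$respondent_id, s$respondent_id)]
  }
  pick("pss14", "total", "pss14_total")
  pick("esi", "total", "esi_total")
  pick("hscl25", "anxiety", "hscl_anxiety")
  pick("hscl25", "depression", "hscl_depression")
  pick("hscl25", "total", "hscl_total")
  pick("scl90r_somatization", "total", "scl_somatization")
  pick("pds_events", "total", "pds_events")
  pick("pds_symptoms", "total", "pds_severity")
  for (sub in c("physical", "verbal_emotional", "sexual", "witnessed",
                "neglect")) {
    pick("cfv", sub, paste0("cfv_", sub))
  }
  pick("cfv", "total", "cfv_total")
  out
}
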