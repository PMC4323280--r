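#' Interview CSV column dictionary
#'
#' Mandatory columns of the wide interview CSV: identifier, context fields,
#' and every raw field a risk indicator is derived from (see
#' [derive_indicators()]). Logical fields accept TRUE/FALSE or 0/1.
#'
#' @return Character vector of mandatory column names.
#' @export
interview_columns <- function() {
  c("respondent_id", "age_years", "gestational_week",
    "mother_foreign_born", "father_foreign_born", "cohabiting_with_father",
    "financial_worry", "rooms", "persons", "pregnancy_planned",
    "joy_mother", "worries_mother", "joy_father", "worries_father",
    paste0("pss4_", 1:4),
    "physical_symptoms", "complications", "medical_risk",
    "childhood_physical_abuse", "childhood_sexual_abuse",
    "ipv_increase_8w", "ipv_vociferous_8w", "ipv_physical_8w", "ipv_ever",
    "smoke_mother", "alcohol_mother", "drugs_mother",
    "smoke_father", "alcohol_father", "drugs_father",
    "psych_diagnosis_ever", "psych_inpatient_ever", "psychotropic_ever",
    "sought_help_ever", "interview_unit", "interviewer_profession")
}

#' @keywords internal
#' @noRd
interview_logical_columns <- function() {
  c("mother_foreign_born", "father_foreign_born", "cohabiting_with_father",
    "financial_worry", "pregnancy_planned", "physical_symptoms",
    "complications", "medical_risk", "childhood_physical_abuse",
    "childhood_sexual_abuse", "ipv_increase_8w", "ipv_vociferous_8w",
    "ipv_physical_8w", "ipv_ever", "smoke_mother", "alcohol_mother",
    "drugs_mother", "smoke_father", "alcohol_father", "drugs_father",
    "psych_diagnosis_ever", "psych_inpatient_ever", "psychotropic_ever",
    "sought_help_ever", "in_validation")
}

#' Read raw interviews from CSV
#'
#' Reads a wide UTF-8 comma-separated interview table (see
#' [interview_columns()]), types the fields, and collects row-level
#' problems instead of dropping them silently: rows with impossible
#' household counts or out-of-range ratings are rejected with a reason and
#' returned in the `issues` attribute. A missing mandatory column is a hard
#' error listing the columns.
#'
#' @param path CSV path.
#' @param dec Decimal mark in the file, default `"."` (set `","` for
#'   locale-formatted exports; the field separator is then `";"`).
#' @return Tibble of typed interviews, with attribute `issues` (tibble
#'   `respondent_id`, `reason`) for rejected rows. Gestational weeks
#'   outside the 24--36 eligibility window produce warnings, not
#'   rejections.
#' @export
read_interviews <- function(path, dec = ".") {
  sep <- if (dec == ",") ";" else ","
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, dec = dec,
                         sep = sep, fileEncoding = "UTF-8")
  missing_cols <- setdiff(interview_columns(), names(raw))
  if (length(missing_cols)) {
    stop("interview table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  iv <- tibble::as_tibble(raw)
  iv$respondent_id <- as.character(iv$respondent_id)
  for (col in intersect(interview_logical_columns(), names(iv))) {
    iv[[col]] <- as.logical(iv[[col]])
  }
  if ("support_wish" %in% names(iv)) {
    iv$support_wish <- as.character(iv$support_wish)
  }
  issues <- list()
  reject <- rep(FALSE, nrow(iv))
  flag <- function(bad, reason) {
    bad <- which(bad)
    if (length(bad)) {
      issues[[length(issues) + 1L]] <<- tibble::tibble(
        respondent_id = iv$respondent_id[bad], reason = reason)
      reject[bad] <<- TRUE
    }
  }
  flag(!is.na(iv$persons) & iv$persons < 1 |
         !is.na(iv$rooms) & iv$rooms < 1,
       "rooms and persons must be positive")
  for (col in c("joy_mother", "worries_mother", "joy_father",
                "worries_father")) {
    flag(!is.na(iv[[col]]) & (iv[[col]] < 0 | iv[[col]] > 10),
         paste0(col, " outside 0-10"))
  }
  for (col in paste0("pss4_", 1:4)) {
    flag(!is.na(iv[[col]]) & (iv[[col]] < 0 | iv[[col]] > 4),
         paste0(col, " outside 0-4"))
  }
  out_window <- !is.na(iv$gestational_week) &
    (iv$gestational_week < 24 | iv$gestational_week > 36)
  if (any(out_window)) {
    warning(sum(out_window),
            " interview(s) outside the 24-36 gestational-week eligibility window",
            call. = FALSE)
  }
  out <- iv[!reject, , drop = FALSE]
  attr(out, "issues") <- if (length(issues)) dplyr::bind_rows(issues) else
    tibble::tibble(respondent_id = character(), reason = character())
  out
}

#' Read a battery response table from CSV
#'
#' Wide format: `respondent_id` plus one column per schema item.
#'
#' @param path CSV path.
#' @param schema The instrument's schema (used to check item columns).
#' @inheritParams read_interviews
#' @return Wide response tibble.
#' @export
read_battery <- function(path, schema, dec = ".") {
  sep <- if (dec == ",") ";" else ","
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, dec = dec,
                         sep = sep, fileEncoding = "UTF-8")
  if (!"respondent_id" %in% names(raw)) {
    stop("battery table lacks respondent_id", call. = FALSE)
  }
  absent <- setdiff(schema$items, names(raw))
  if (length(absent)) {
    stop("battery table for ", schema$instrument_id,
         " lacks item column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(raw[c("respondent_id", schema$items)])
  out$respondent_id <- as.character(out$respondent_id)
  out
}

#' Write a cohort to a directory of plain-text files
#'
#' Writes `interviews.csv`, one `battery_<instrument>.csv` per instrument,
#' and `ground_truth.json` (latent adversity values plus the generator
#' configuration) into `dir`. All files are UTF-8, comma-separated,
#' "."-decimal.
#'
#' @param cohort A `kindex_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$interviews, file.path(dir, "interviews.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  for (inst in names(cohort$battery)) {
    utils::write.csv(cohort$battery[[inst]],
                     file.path(dir, paste0("battery_", inst, ".csv")),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  truth <- list(latent = cohort$latent,
                config = unclass(cohort$config))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort back from a directory written by [write_cohort()]
#'
#' @param dir Directory containing `interviews.csv` and the battery CSVs.
#' @return A `kindex_cohort` (with `latent`/`config` populated when
#'   `ground_truth.json` is present).
#' @export
read_cohort <- function(dir) {
  interviews <- read_interviews(file.path(dir, "interviews.csv"))
  schemas <- kindex_schemas()
  files <- list.files(dir, pattern = "^battery_.*\\.csv$")
  battery <- list()
  for (f in files) {
    inst <- sub("^battery_(.*)\\.csv$", "\\1", f)
    battery[[inst]] <- read_battery(file.path(dir, f), schemas[[inst]])
  }
  latent <- NULL; config <- NULL
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    truth <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    latent <- tibble::as_tibble(truth$latent)
    config <- truth$config
  }
  structure(list(interviews = interviews, battery = battery,
                 latent = latent, config = config),
            class = "kindex_cohort")
}

#' Run the full concurrent-validity analysis pipeline
#'
#' Executes every analysis stage on a cohort: risk-indicator derivation and
#' sum score, cohort descriptives, battery scoring, global composites,
#' the Lilliefors normality gate, Spearman correlations between the sum
#' score and the composites, reliability of the dichotomized items with
#' zero-variance exclusion, item-criterion group comparisons (psychiatric
#' diagnosis vs the psychopathology scales; childhood physical abuse vs the
#' family-violence subscales), and the interviewer-profession and
#' hospital-unit comparisons. Every option and the seed are echoed in the
#' bundle; the number of significance tests performed is recorded, and no
#' multiple-testing correction is applied.
#'
#' @param cohort A `kindex_cohort` (or any list with `interviews` and
#'   `battery` in the same layout).
#' @param alpha Decision level for the normality gate, default 0.05.
#' @param sd_type SD convention for z-transforms, see [z_transform()].
#' @param housing_cmp Housing-rule comparator, see [derive_indicators()].
#' @param referral_threshold Referral threshold, default 2.
#' @param one_sided Report one-sided p for the interviewer t test, default
#'   `FALSE`.
#' @return List of class `kindex_report`: `profile`, `descriptives`,
#'   `scores`, `battery_summary`, `composites`, `normality`,
#'   `correlations`, `reliability`, `item_comparisons` (named list),
#'   `unit_comparison`, `interviewer_comparison`, `notes`, `options`,
#'   `n_tests`.
#' @export
run_validation_pipeline <- function(cohort, alpha = 0.05,
                                    sd_type = "sample",
                                    housing_cmp = "<=",
                                    referral_threshold = 2,
                                    one_sided = FALSE) {
  if (is.null(cohort$interviews) || !nrow(cohort$interviews)) {
    stop("pipeline stage 'input': empty cohort", call. = FALSE)
  }
  notes <- character()
  note <- function(msg) notes <<- c(notes, msg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  profile <- stage("risk_profile",
                   risk_profile(cohort$interviews, housing_cmp = housing_cmp,
                                referral_threshold = referral_threshold))
  desc <- stage("descriptives", descriptives(profile, cohort$interviews))
  scores <- stage("score_battery", score_battery(cohort$battery))
  comps <- stage("composites", compute_composites(scores, sd_type = sd_type))

  analysis <- dplyr::inner_join(
    profile[, c("respondent_id", "sum_score")], comps, by = "respondent_id")
  analysis <- dplyr::inner_join(analysis, scores, by = "respondent_id")

  summarize_scale <- function(x, name) {
    ok <- !is.na(x)
    tibble::tibble(scale = name, n = sum(ok), mean = mean(x[ok]),
                   sd = stats::sd(x[ok]), median = stats::median(x[ok]),
                   min = min(x[ok]), max = max(x[ok]))
  }
  battery_cols <- c("pss14_total", "esi_total", "global_stress",
                    "hscl_depression", "hscl_anxiety", "scl_somatization",
                    "pds_severity", "global_psychopathology", "cfv_total",
                    "pds_events", "global_trauma_load")
  battery_summary <- dplyr::bind_rows(
    lapply(battery_cols, function(cl) summarize_scale(analysis[[cl]], cl)))

  norm_vars <- c("sum_score", "global_stress", "global_psychopathology",
                 "global_trauma_load")
  normality <- dplyr::bind_rows(lapply(norm_vars, function(v) {
    r <- tryCatch(ks_normality(analysis[[v]], alpha = alpha, variable = v),
                  error = function(e) {
                    note(paste0("normality gate skipped for ", v, ": ",
                                conditionMessage(e)))
                    NULL
                  })
    if (is.null(r)) {
      tibble::tibble(variable = v, D = NA_real_, n = sum(!is.na(analysis[[v]])),
                     p = NA_real_, normal = NA)
    } else {
      tibble::tibble(variable = r$variable, D = r$D, n = r$n, p = r$p,
                     normal = r$normal)
    }
  }))

  correlations <- stage("correlations",
                        spearman_matrix(analysis[norm_vars]))

  reliability <- stage("reliability", {
    reg <- kindex_indicator_registry()
    cronbach_alpha(as.matrix(profile[reg$indicator]) * 1)
  })

  compare <- function(indicator_col, criteria_cols, label) {
    ind <- profile[[indicator_col]][match(analysis$respondent_id,
                                          profile$respondent_id)]
    tryCatch(item_criterion_comparison(ind, analysis[criteria_cols]),
             error = function(e) {
               note(paste0("item comparison '", label, "' skipped: ",
                           conditionMessage(e)))
               NULL
             })
  }
  item_comparisons <- list(
    psych_diagnosis = compare(
      "psych_diagnosis_ever",
      c("scl_somatization", "pds_severity", "hscl_depression",
        "hscl_anxiety"),
      "psychiatric diagnosis"),
    childhood_physical_abuse = compare(
      "childhood_physical_abuse",
      c("cfv_total", "cfv_physical", "cfv_witnessed",
        "cfv_verbal_emotional", "cfv_neglect", "cfv_sexual"),
      "childhood physical abuse"))

  iv <- cohort$interviews
  sum_all <- profile$sum_score[match(iv$respondent_id,
                                     profile$respondent_id)]
  unit_comparison <- tryCatch(
    kruskal_wallis(split(sum_all, iv$interview_unit)),
    error = function(e) { note(paste0("unit comparison skipped: ",
                                      conditionMessage(e))); NULL })
  interviewer_comparison <- tryCatch({
    gr <- split(sum_all, iv$interviewer_profession)
    student_t(gr[[1]], gr[[2]], one_sided = one_sided)
  }, error = function(e) { note(paste0("interviewer comparison skipped: ",
                                       conditionMessage(e))); NULL })

  n_tests <- nrow(correlations) + nrow(normality) +
    sum(vapply(item_comparisons, function(x) if (is.null(x)) 0L else nrow(x),
               integer(1))) +
    (!is.null(unit_comparison)) + (!is.null(interviewer_comparison)) +
    sum(!is.na(desc$indicators$p_diff)) +
    if (is.null(desc$ratings)) 0L else sum(!is.na(desc$ratings$p_diff))

  structure(list(
    profile = profile, descriptives = desc, scores = scores,
    battery_summary = battery_summary, composites = comps,
    normality = normality, correlations = correlations,
    reliability = reliability, item_comparisons = item_comparisons,
    unit_comparison = unit_comparison,
    interviewer_comparison = interviewer_comparison,
    notes = notes,
    options = list(alpha = alpha, sd_type = sd_type,
                   housing_cmp = housing_cmp,
                   referral_threshold = referral_threshold,
                   one_sided = one_sided,
                   seed = if (!is.null(cohort$config))
                     cohort$config$seed else NA_integer_,
                   multiple_testing_correction = "none"),
    n_tests = n_tests),
    class = "kindex_report")
}

#' @export
print.kindex_report <- function(x, ...) {
  cat("<kindex_report> n = ", nrow(x$profile), ", battery n = ",
      nrow(x$scores), "\n", sep = "")
  cat("  reliability: alpha = ", format(round(x$reliability$alpha, 3)),
      " (", x$reliability$n_items_retained, " items retained)\n", sep = "")
  cat("  correlations (sum score vs composites):\n")
  print(dplyr::filter(tibble::as_tibble(x$correlations),
                      .data$var1 == "sum_score"))
  cat("  ", x$n_tests, " significance tests performed (no multiplicity correction)\n",
      sep = "")
  if (length(x$notes)) cat("  notes: ", paste(x$notes, collapse = "; "),
                           "\n", sep = "")
  invisible(x)
}

#' @keywords internal
#' @noRd
md_table <- function(df, digits = 3) {
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "", format(round(x, digits))) else
      ifelse(is.na(x), "", as.character(x))
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "),
                                              " |"))
  c(header, rule, body)
}

#' Render a pipeline report bundle as Markdown
#'
#' Writes analogues of the standard validation-study tables (risk-factor
#' descriptives, battery summary, correlation matrix, item-criterion
#' comparisons) plus reliability, normality, and the exact option set used.
#'
#' @param report A `kindex_report` from [run_validation_pipeline()].
#' @param path Output `.md` path.
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path) {
  L <- c("# KINDEX concurrent-validity report", "")
  add <- function(...) L <<- c(L, ...)
  add("## Risk-factor descriptives", "",
      md_table(report$descriptives$indicators), "")
  if (!is.null(report$descriptives$ratings)) {
    add("### Rating and score means", "",
        md_table(report$descriptives$ratings), "")
  }
  add("## Validation battery summary", "",
      md_table(report$battery_summary), "")
  add("## Normality screening (Lilliefors)", "",
      md_table(report$normality, digits = 4), "")
  add("## Spearman correlations", "",
      md_table(tibble::as_tibble(report$correlations), digits = 4), "")
  rel <- report$reliability
  add("## Reliability",
      "",
      sprintf("Cronbach's alpha = %.3f over %d of %d items (n = %d).",
              rel$alpha, rel$n_items_retained, rel$n_items_input,
              rel$n_respondents),
      if (nrow(rel$excluded_items))
        sprintf("Excluded for zero variation: %s.",
                paste(rel$excluded_items$item, collapse = ", "))
      else "No zero-variance exclusions.", "")
  for (nm in names(report$item_comparisons)) {
    tab <- report$item_comparisons[[nm]]
    if (!is.null(tab)) {
      add(paste0("## Item-criterion comparisons: ", nm), "",
          md_table(tab), "")
    }
  }
  if (!is.null(report$unit_comparison)) {
    u <- report$unit_comparison
    add(sprintf("Hospital-unit comparison: H(%d) = %.2f, p = %.3f.",
                u$df, u$statistic, u$p), "")
  }
  if (!is.null(report$interviewer_comparison)) {
    tt <- report$interviewer_comparison
    add(sprintf("Interviewer-profession comparison: t(%d) = %.2f, p = %.3f.",
                round(tt$df), tt$statistic, tt$p), "")
  }
  opts <- report$options
  add("## Options",
      "",
      sprintf("- alpha: %s", opts$alpha),
      sprintf("- SD convention: %s", opts$sd_type),
      sprintf("- housing comparator: %s 0.5", opts$housing_cmp),
      sprintf("- referral threshold: %s", opts$referral_threshold),
      sprintf("- one-sided t: %s", opts$one_sided),
      sprintf("- seed: %s", opts$seed),
      sprintf("- multiple-testing correction: %s; %d tests performed",
              opts$multiple_testing_correction, report$n_tests), "")
  if (length(report$notes)) {
    add("## Notes", "", paste0("- ", report$notes), "")
  }
  writeLines(L, path, useBytes = TRUE)
  invisible(path)
}
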