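#' The 31 KINDEX risk indicators and their 11 risk areas
#'
#' Registry of the dichotomous risk indicators derived from a KINDEX
#' interview, tagged with their risk area. Area item counts are fixed at
#' (age 1, migration 2, single_parent 1, financial 2, medical 3, bonding 5,
#' stress 1, childhood_trauma 2, ipv 4, substance 6, mental_illness 4),
#' i.e. 31 indicators over 11 areas.
#'
#' @return Tibble with columns `indicator` and `area`.
#' @export
kindex_indicator_registry <- function() {
  tibble::tribble(
    ~indicator,                ~area,
    "age_under_21",            "age",
    "mother_foreign_born",     "migration",
    "father_foreign_born",     "migration",
    "single_parent",           "single_parent",
    "financial_worry",         "financial",
    "housing_crowded",         "financial",
    "physical_symptoms",       "medical",
    "complications",           "medical",
    "medical_risk",            "medical",
    "unplanned_pregnancy",     "bonding",
    "low_joy_mother",          "bonding",
    "high_worries_mother",     "bonding",
    "low_joy_father",          "bonding",
    "high_worries_father",     "bonding",
    "high_perceived_stress",   "stress",
    "childhood_physical_abuse","childhood_trauma",
    "childhood_sexual_abuse",  "childhood_trauma",
    "ipv_increase_8w",         "ipv",
    "ipv_vociferous_8w",       "ipv",
    "ipv_physical_8w",         "ipv",
    "ipv_ever",                "ipv",
    "smoke_mother",            "substance",
    "alcohol_mother",          "substance",
    "drugs_mother",            "substance",
    "smoke_father",            "substance",
    "alcohol_father",          "substance",
    "drugs_father",            "substance",
    "psych_diagnosis_ever",    "mental_illness",
    "psych_inpatient_ever",    "mental_illness",
    "psychotropic_ever",       "mental_illness",
    "sought_help_ever",        "mental_illness"
  )
}

#' Housing index (rooms per person)
#'
#' The crowding basis of the financial risk area: rooms divided by persons
#' living in the household. A ratio at or below 0.5 counts as a risk under
#' the default comparator (see [derive_indicators()]).
#'
#' @param rooms,persons Positive integer vectors (recycled).
#' @return Numeric vector `rooms / persons`.
#' @export
#' @examples
#' housing_index(1, 2)   # 0.5 -> risk under the default <= 0.5 rule
housing_index <- function(rooms, persons) {
  bad <- which(!is.na(rooms) & rooms < 1 | !is.na(persons) & persons < 1)
  if (length(bad)) {
    stop("rooms and persons must be positive integers (offending position(s): ",
         paste(utils::head(bad, 5), collapse = ", "), ")", call. = FALSE)
  }
  rooms / persons
}

#' PSS-4 perceived-stress sum and risk flag
#'
#' Scores the four embedded PSS-4 items (after schema reverse coding; two
#' items are reverse keyed by default) and dichotomizes at the upper-quartile
#' cutoff: a total of 12 or more, out of the attainable 0--16, flags
#' high perceived stress.
#'
#' @param pss4_items Matrix or data frame with 4 columns (items in schema
#'   order, raw 0--4 responses), or a length-4 vector for one respondent.
#' @param cutoff Risk cutoff on the reverse-coded sum, default 12.
#' @param schema PSS-4 schema, default the built-in one.
#' @return Tibble with `pss4_sum` and logical `pss4_risk` (both `NA` for
#'   respondents with any missing item).
#' @export
#' @examples
#' pss4_stress_risk(c(4, 0, 0, 4))   # raw items; reverse-keyed items reflect
pss4_stress_risk <- function(pss4_items, cutoff = 12,
                             schema = kindex_schemas("pss4")) {
  if (is.null(dim(pss4_items))) pss4_items <- matrix(pss4_items, nrow = 1)
  pss4_items <- as.matrix(pss4_items)
  if (ncol(pss4_items) != length(schema$items)) {
    stop("expected ", length(schema$items), " PSS-4 item columns", call. = FALSE)
  }
  colnames(pss4_items) <- schema$items
  resp <- tibble::as_tibble(pss4_items)
  resp$respondent_id <- as.character(seq_len(nrow(resp)))
  sc <- score_instrument(schema, resp)
  tibble::tibble(pss4_sum = sc$total, pss4_risk = sc$total >= cutoff)
}

#' Derive the 31 dichotomous risk indicators from raw interviews
#'
#' Applies the fixed recoding rules of the screening instrument to each raw
#' interview record:
#' * maternal age 21 years or younger;
#' * mother or father born abroad;
#' * not cohabiting with the child's father (single parent);
#' * worry about financial problems; housing index at most 0.5 rooms/person;
#' * physical symptoms, pregnancy complications, medical risk factors;
#' * unplanned pregnancy; parental bonding ratings recoded at the extreme
#'   quartiles (joy 0--3, worries 7--10, for mother and father);
#' * PSS-4 sum at or above 12;
#' * childhood physical or sexual abuse;
#' * the four intimate-partner-violence questions;
#' * the six substance questions (nicotine/alcohol/drugs, mother and father);
#' * the four mental-health history questions.
#'
#' All cutpoints are fixed recode constants, not sample quantiles. A missing
#' raw field yields a missing indicator (complete-case handling downstream).
#'
#' @param interviews Tibble of raw interviews (see [read_interviews()] for
#'   the column dictionary).
#' @param housing_cmp Comparator for the housing rule, `"<="` (default,
#'   the operational rule-sheet convention) or `"<"`.
#' @param age_cutoff Age risk cutoff in years (risk when `age <= age_cutoff`),
#'   default 21.
#' @param pss4_cutoff PSS-4 risk cutoff, default 12.
#' @return Tibble: `respondent_id` plus 31 logical indicator columns in
#'   registry order.
#' @export
derive_indicators <- function(interviews, housing_cmp = c("<=", "<"),
                              age_cutoff = 21, pss4_cutoff = 12) {
  housing_cmp <- match.arg(housing_cmp)
  iv <- interviews
  rating_cols <- c("joy_mother", "worries_mother", "joy_father",
                   "worries_father")
  for (col in rating_cols) {
    bad <- which(!is.na(iv[[col]]) & (iv[[col]] < 0 | iv[[col]] > 10))
    if (length(bad)) {
      stop("rating ", col, " out of 0-10 range for respondent(s) ",
           paste(utils::head(iv$respondent_id[bad], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  hi <- housing_index(iv$rooms, iv$persons)
  housing_risk <- if (housing_cmp == "<=") hi <= 0.5 else hi < 0.5
  pss4 <- pss4_stress_risk(as.matrix(iv[paste0("pss4_", 1:4)]),
                           cutoff = pss4_cutoff)
  tibble::tibble(
    respondent_id = iv$respondent_id,
    age_under_21 = iv$age_years <= age_cutoff,
    mother_foreign_born = as.logical(iv$mother_foreign_born),
    father_foreign_born = as.logical(iv$father_foreign_born),
    single_parent = !iv$cohabiting_with_father,
    financial_worry = as.logical(iv$financial_worry),
    housing_crowded = housing_risk,
    physical_symptoms = as.logical(iv$physical_symptoms),
    complications = as.logical(iv$complications),
    medical_risk = as.logical(iv$medical_risk),
    unplanned_pregnancy = !iv$pregnancy_planned,
    low_joy_mother = iv$joy_mother <= 3,
    high_worries_mother = iv$worries_mother >= 7,
    low_joy_father = iv$joy_father <= 3,
    high_worries_father = iv$worries_father >= 7,
    high_perceived_stress = pss4$pss4_risk,
    childhood_physical_abuse = as.logical(iv$childhood_physical_abuse),
    childhood_sexual_abuse = as.logical(iv$childhood_sexual_abuse),
    ipv_increase_8w = as.logical(iv$ipv_increase_8w),
    ipv_vociferous_8w = as.logical(iv$ipv_vociferous_8w),
    ipv_physical_8w = as.logical(iv$ipv_physical_8w),
    ipv_ever = as.logical(iv$ipv_ever),
    smoke_mother = as.logical(iv$smoke_mother),
    alcohol_mother = as.logical(iv$alcohol_mother),
    drugs_mother = as.logical(iv$drugs_mother),
    smoke_father = as.logical(iv$smoke_father),
    alcohol_father = as.logical(iv$alcohol_father),
    drugs_father = as.logical(iv$drugs_father),
    psych_diagnosis_ever = as.logical(iv$psych_diagnosis_ever),
    psych_inpatient_ever = as.logical(iv$psych_inpatient_ever),
    psychotropic_ever = as.logical(iv$psychotropic_ever),
    sought_help_ever = as.logical(iv$sought_help_ever)
  )
}

#' Risk sum score
#'
#' Count of true indicators over the full 31-indicator set. Under
#' complete-case handling the sum is missing when any indicator is missing;
#' per-area partial counts (over the non-missing indicators) are still
#' reported for diagnostics.
#'
#' @param indicators Tibble from [derive_indicators()].
#' @return Tibble: `respondent_id`, `sum_score` (integer, `NA` when any
#'   indicator is missing), `n_missing_indicators`, and one
#'   `area_<name>` partial count per risk area.
#' @export
sum_score <- function(indicators) {
  reg <- kindex_indicator_registry()
  m <- as.matrix(indicators[reg$indicator])
  total <- rowSums(m)                         # NA if any indicator missing
  out <- tibble::tibble(
    respondent_id = indicators$respondent_id,
    sum_score = as.integer(total),
    n_missing_indicators = rowSums(is.na(m)))
  for (a in unique(reg$area)) {
    cols <- reg$indicator[reg$area == a]
    out[[paste0("area_", a)]] <-
      as.integer(rowSums(m[, cols, drop = FALSE], na.rm = TRUE))
  }
  out
}

#' Referral flag
#'
#' Screening-positive decision rule: flag a respondent for referral to
#' psychosocial services when the risk sum score reaches the threshold
#' (default: 2 or more risks).
#'
#' @param sum_score Integer vector of risk sum scores.
#' @param threshold Referral threshold, default 2.
#' @return Logical vector (`NA` where the sum is missing).
#' @export
flag_referral <- function(sum_score, threshold = 2) {
  sum_score >= threshold
}

#' Full risk profile
#'
#' Convenience wrapper chaining [derive_indicators()], [sum_score()] and
#' [flag_referral()].
#'
#' @inheritParams derive_indicators
#' @param referral_threshold Threshold passed to [flag_referral()].
#' @return Tibble: `respondent_id`, the 31 indicators, the area counts,
#'   `sum_score`, `referral_flag`.
#' @export
risk_profile <- function(interviews, housing_cmp = "<=", age_cutoff = 21,
                         pss4_cutoff = 12, referral_threshold = 2) {
  ind <- derive_indicators(interviews, housing_cmp = housing_cmp,
                           age_cutoff = age_cutoff, pss4_cutoff = pss4_cutoff)
  ss <- sum_score(ind)
  out <- dplyr::left_join(ind, ss, by = "respondent_id")
  out$referral_flag <- flag_referral(out$sum_score,
                                     threshold = referral_threshold)
  out
}
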