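# Fixture builders used across the suite. All interview fields default to
# the fully benign respondent; override any field to switch on a risk.
# Note the PSS-4 raw items: items 2 and 3 are reverse keyed, so the benign
# raw pattern is (0, 4, 4, 0) (scored sum 0) and the maximal-stress raw
# pattern is (4, 0, 0, 4) (scored sum 16).

make_interview <- function(n = 1, ...) {
  base <- tibble::tibble(
    respondent_id = sprintf("P%03d", seq_len(n)),
    age_years = 30, gestational_week = 30,
    mother_foreign_born = FALSE, father_foreign_born = FALSE,
    cohabiting_with_father = TRUE, financial_worry = FALSE,
    rooms = 3L, persons = 2L, pregnancy_planned = TRUE,
    joy_mother = 10, worries_mother = 0, joy_father = 10, worries_father = 0,
    pss4_1 = 0, pss4_2 = 4, pss4_3 = 4, pss4_4 = 0,
    physical_symptoms = FALSE, complications = FALSE, medical_risk = FALSE,
    childhood_physical_abuse = FALSE, childhood_sexual_abuse = FALSE,
    ipv_increase_8w = FALSE, ipv_vociferous_8w = FALSE,
    ipv_physical_8w = FALSE, ipv_ever = FALSE,
    smoke_mother = FALSE, alcohol_mother = FALSE, drugs_mother = FALSE,
    smoke_father = FALSE, alcohol_father = FALSE, drugs_father = FALSE,
    psych_diagnosis_ever = FALSE, psych_inpatient_ever = FALSE,
    psychotropic_ever = FALSE, sought_help_ever = FALSE,
    interview_unit = "outpatient", interviewer_profession = "midwife",
    support_wish = NA_character_)
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

# every raw condition switched to its risk state
make_maximal_interview <- function() {
  make_interview(
    age_years = 19, mother_foreign_born = TRUE, father_foreign_born = TRUE,
    cohabiting_with_father = FALSE, financial_worry = TRUE,
    rooms = 1L, persons = 3L, pregnancy_planned = FALSE,
    joy_mother = 0, worries_mother = 10, joy_father = 0, worries_father = 10,
    pss4_1 = 4, pss4_2 = 0, pss4_3 = 0, pss4_4 = 4,
    physical_symptoms = TRUE, complications = TRUE, medical_risk = TRUE,
    childhood_physical_abuse = TRUE, childhood_sexual_abuse = TRUE,
    ipv_increase_8w = TRUE, ipv_vociferous_8w = TRUE, ipv_physical_8w = TRUE,
    ipv_ever = TRUE, smoke_mother = TRUE, alcohol_mother = TRUE,
    drugs_mother = TRUE, smoke_father = TRUE, alcohol_father = TRUE,
    drugs_father = TRUE, psych_diagnosis_ever = TRUE,
    psych_inpatient_ever = TRUE, psychotropic_ever = TRUE,
    sought_help_ever = TRUE)
}

# wide response table for a schema with every respondent at a fixed value
make_responses <- function(schema, values) {
  n <- if (is.null(dim(values))) 1L else nrow(values)
  m <- matrix(values, nrow = n, ncol = length(schema$items), byrow = is.null(dim(values)))
  colnames(m) <- schema$items
  out <- tibble::as_tibble(as.data.frame(m))
  tibble::add_column(out, respondent_id = sprintf("S%03d", seq_len(n)),
                     .before = 1)
}

# random valid wide responses for a schema
random_responses <- function(schema, n) {
  m <- matrix(sample(schema$response_min:schema$response_max,
                     n * length(schema$items), replace = TRUE),
              nrow = n)
  colnames(m) <- schema$items
  out <- tibble::as_tibble(as.data.frame(m))
  tibble::add_column(out, respondent_id = sprintf("S%03d", seq_len(n)),
                     .before = 1)
}

# a default-condition synthetic cohort in which the three structurally
# zero-prevalence indicators are constant and every other indicator varies;
# advances the seed deterministically until the variation condition holds
make_reliability_cohort <- function(n = 200, seed = 1) {
  structural_zero <- c("single_parent", "drugs_mother",
                       "psych_inpatient_ever")
  varying <- setdiff(kindex_indicator_registry()$indicator, structural_zero)
  repeat {
    cohort <- generate_cohort(generator_config(n = n, seed = seed))
    ind <- derive_indicators(cohort$interviews)
    m <- as.matrix(ind[varying]) * 1
    if (all(apply(m, 2, stats::var) > 0)) return(cohort)
    seed <- seed + 1
  }
}
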