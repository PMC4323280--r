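test_that("housing index arithmetic and risk rule", {
  expect_equal(housing_index(1, 2), 0.5)
  expect_equal(housing_index(3, 2), 1.5)
  expect_equal(housing_index(2, 5), 0.4)
  expect_error(housing_index(0, 2), "positive")
  expect_error(housing_index(2, 0), "positive")

  iv <- make_interview(n = 3)
  iv$rooms <- c(1L, 3L, 2L); iv$persons <- c(2L, 2L, 5L)
  ind <- derive_indicators(iv)
  expect_equal(ind$housing_crowded, c(TRUE, FALSE, TRUE))
  # strict comparator: 0.5 no longer flips
  ind_strict <- derive_indicators(iv, housing_cmp = "<")
  expect_equal(ind_strict$housing_crowded, c(FALSE, FALSE, TRUE))
})

test_that("PSS-4 sum and upper-quartile risk flag", {
  # raw patterns: items 2 and 3 are reverse keyed
  max_stress <- pss4_stress_risk(c(4, 0, 0, 4))
  expect_equal(max_stress$pss4_sum, 16)
  expect_true(max_stress$pss4_risk)
  none <- pss4_stress_risk(c(0, 4, 4, 0))
  expect_equal(none$pss4_sum, 0)
  expect_false(none$pss4_risk)
  # scored (3,3,3,2) -> raw (3,1,1,2): boundary just below the cutoff
  eleven <- pss4_stress_risk(c(3, 1, 1, 2))
  expect_equal(eleven$pss4_sum, 11)
  expect_false(eleven$pss4_risk)
  twelve <- pss4_stress_risk(c(3, 1, 1, 3))
  expect_equal(twelve$pss4_sum, 12)
  expect_true(twelve$pss4_risk)
  # missing item propagates
  miss <- pss4_stress_risk(c(3, NA, 1, 3))
  expect_true(is.na(miss$pss4_sum))
  expect_true(is.na(miss$pss4_risk))
})

test_that("benign, single-risk and maximal archetypes score 0, 1 and 31", {
  reg <- kindex_indicator_registry()
  benign <- derive_indicators(make_interview())
  expect_true(all(!as.matrix(benign[reg$indicator])))
  expect_equal(sum_score(benign)$sum_score, 0L)

  young <- derive_indicators(make_interview(age_years = 20))
  expect_true(young$age_under_21)
  expect_equal(sum_score(young)$sum_score, 1L)

  maximal <- derive_indicators(make_maximal_interview())
  expect_true(all(as.matrix(maximal[reg$indicator])))
  expect_equal(sum_score(maximal)$sum_score, 31L)
})

test_that("every dichotomization boundary flips exactly at its cutpoint", {
  flips <- list(
    list(field = "age_years", risk = 21, safe = 22, ind = "age_under_21"),
    list(field = "joy_mother", risk = 3, safe = 4, ind = "low_joy_mother"),
    list(field = "worries_mother", risk = 7, safe = 6,
         ind = "high_worries_mother"),
    list(field = "joy_father", risk = 3, safe = 4, ind = "low_joy_father"),
    list(field = "worries_father", risk = 7, safe = 6,
         ind = "high_worries_father"))
  for (f in flips) {
    iv_risk <- make_interview(); iv_risk[[f$field]] <- f$risk
    iv_safe <- make_interview(); iv_safe[[f$field]] <- f$safe
    expect_true(derive_indicators(iv_risk)[[f$ind]], label = f$ind)
    expect_false(derive_indicators(iv_safe)[[f$ind]], label = f$ind)
  }
})

test_that("derived sum is monotone in the raw risk conditions", {
  set.seed(31)
  bool_fields <- c("mother_foreign_born", "father_foreign_born",
                   "financial_worry", "physical_symptoms", "complications",
                   "medical_risk", "childhood_physical_abuse",
                   "childhood_sexual_abuse", "ipv_increase_8w",
                   "ipv_vociferous_8w", "ipv_physical_8w", "ipv_ever",
                   "smoke_mother", "alcohol_mother", "drugs_mother",
                   "smoke_father", "alcohol_father", "drugs_father",
                   "psych_diagnosis_ever", "psych_inpatient_ever",
                   "psychotropic_ever", "sought_help_ever")
  for (rep in 1:20) {
    iv <- make_interview()
    on <- sample(bool_fields, sample(0:8, 1))
    for (f in on) iv[[f]] <- TRUE
    base <- sum_score(derive_indicators(iv))$sum_score
    extra <- sample(setdiff(bool_fields, on), 1)
    iv2 <- iv; iv2[[extra]] <- TRUE
    expect_gte(sum_score(derive_indicators(iv2))$sum_score, base)
    # and tightening a rating or the age can only add risk
    iv3 <- iv; iv3$age_years <- 19; iv3$joy_mother <- 2
    expect_gte(sum_score(derive_indicators(iv3))$sum_score, base)
  }
})

test_that("sum score equals an independent rule-by-rule re-derivation", {
  set.seed(32)
  n <- 60
  iv <- make_interview(n = n)
  iv$age_years <- sample(18:42, n, replace = TRUE)
  iv$mother_foreign_born <- sample(c(TRUE, FALSE), n, replace = TRUE)
  iv$father_foreign_born <- sample(c(TRUE, FALSE), n, replace = TRUE)
  iv$cohabiting_with_father <- sample(c(TRUE, FALSE), n, replace = TRUE)
  iv$financial_worry <- sample(c(TRUE, FALSE), n, replace = TRUE)
  iv$rooms <- sample(1:4, n, replace = TRUE)
  iv$persons <- sample(1:6, n, replace = TRUE)
  iv$pregnancy_planned <- sample(c(TRUE, FALSE), n, replace = TRUE)
  for (cl in c("joy_mother", "worries_mother", "joy_father",
               "worries_father")) {
    iv[[cl]] <- sample(0:10, n, replace = TRUE)
  }
  for (cl in paste0("pss4_", 1:4)) iv[[cl]] <- sample(0:4, n, replace = TRUE)
  bools <- c("physical_symptoms", "complications", "medical_risk",
             "childhood_physical_abuse", "childhood_sexual_abuse",
             "ipv_increase_8w", "ipv_vociferous_8w", "ipv_physical_8w",
             "ipv_ever", "smoke_mother", "alcohol_mother", "drugs_mother",
             "smoke_father", "alcohol_father", "drugs_father",
             "psych_diagnosis_ever", "psych_inpatient_ever",
             "psychotropic_ever", "sought_help_ever")
  for (cl in bools) iv[[cl]] <- sample(c(TRUE, FALSE), n, replace = TRUE)

  got <- sum_score(derive_indicators(iv))$sum_score

  # independent oracle: each published recode rule applied one by one
  pss4_scored <- iv$pss4_1 + (4 - iv$pss4_2) + (4 - iv$pss4_3) + iv$pss4_4
  oracle <- (iv$age_years <= 21) + iv$mother_foreign_born +
    iv$father_foreign_born + (!iv$cohabiting_with_father) +
    iv$financial_worry + (iv$rooms / iv$persons <= 0.5) +
    iv$physical_symptoms + iv$complications + iv$medical_risk +
    (!iv$pregnancy_planned) + (iv$joy_mother <= 3) +
    (iv$worries_mother >= 7) + (iv$joy_father <= 3) +
    (iv$worries_father >= 7) + (pss4_scored >= 12) +
    iv$childhood_physical_abuse + iv$childhood_sexual_abuse +
    iv$ipv_increase_8w + iv$ipv_vociferous_8w + iv$ipv_physical_8w +
    iv$ipv_ever + iv$smoke_mother + iv$alcohol_mother + iv$drugs_mother +
    iv$smoke_father + iv$alcohol_father + iv$drugs_father +
    iv$psych_diagnosis_ever + iv$psych_inpatient_ever +
    iv$psychotropic_ever + iv$sought_help_ever
  expect_equal(got, as.integer(oracle))
})

test_that("area counts partition the sum and missingness propagates", {
  reg <- kindex_indicator_registry()
  expect_equal(nrow(reg), 31L)
  expect_equal(length(unique(reg$area)), 11L)

  iv <- make_interview(joy_mother = 0, worries_mother = 9, joy_father = 1,
                       worries_father = 8, pregnancy_planned = FALSE)
  ss <- sum_score(derive_indicators(iv))
  expect_equal(ss$sum_score, 5L)           # the five bonding indicators
  expect_equal(ss$area_bonding, 5L)
  area_cols <- paste0("area_", unique(reg$area))
  expect_equal(sum(unlist(ss[area_cols])), 5L)

  # a missing raw field blanks the indicator and the sum, but partial area
  # counts remain available
  iv2 <- make_interview(smoke_father = NA)
  ss2 <- sum_score(derive_indicators(iv2))
  expect_true(is.na(ss2$sum_score))
  expect_equal(ss2$n_missing_indicators, 1)
  expect_equal(ss2$area_substance, 0L)
})

test_that("referral flag thresholds at two or more risks", {
  expect_false(flag_referral(0))
  expect_false(flag_referral(1))
  expect_true(flag_referral(2))
  expect_true(flag_referral(14))
  expect_true(is.na(flag_referral(NA_integer_)))
  expect_false(flag_referral(2, threshold = 3))

  prof <- risk_profile(make_maximal_interview())
  expect_true(prof$referral_flag)
  expect_equal(prof$sum_score, 31L)
})

test_that("out-of-range ratings are a validation error", {
  iv <- make_interview(joy_mother = 11)
  expect_error(derive_indicators(iv), "joy_mother")
})
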