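---
title: "Methods: scoring, composites, statistics and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, composites, statistics and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kindexr)
```

## The screening model

The KINDEX is a structured prenatal interview producing 31 dichotomous
risk indicators across 11 risk areas (age; migration; single parenthood;
financial problems; medical risks; prenatal bonding; current stress;
childhood trauma; intimate partner violence; substance use; mental
illness). Every indicator is a fixed, pre-registered recode of a raw
answer — no cutpoint is estimated from the sample:

| rule | cutpoint | direction |
|---|---|---|
| maternal age | 21 years | risk when ≤ 21 |
| bonding: joy (mother, father) | 0–10 rating | risk when ≤ 3 (lower quartile of the scale) |
| bonding: worries (mother, father) | 0–10 rating | risk when ≥ 7 (upper quartile) |
| perceived stress (PSS-4) | sum of 4 items, 0–16 | risk when ≥ 12 (upper quartile) |
| household crowding | rooms / persons | risk when ≤ 0.5 |

All remaining indicators pass binary interview answers through
unchanged. The risk **sum score** is the count of positive indicators
(0–31), and the **referral flag** marks a sum of 2 or more (threshold
configurable). Because the cutpoints are constants, the scoring engine is
deterministic, total, and monotone: switching any raw answer to its risk
state can never lower the sum — a property the test suite checks over
randomized interviews.

Two cutpoint conventions deserve a note. The crowding rule is stated
ambiguously in the screening literature ("less than 0.5" in prose,
"≤ 0.5" in rule sheets); this package follows the rule-sheet convention
(`<=`), because the rule sheet is the operational instrument, and exposes
the comparator (`housing_cmp`) so either reading can be run. Second, the
full 31-item set always enters the sum score; the 28-item subset that
appears in reliability work arises *only* from the zero-variance exclusion
inside `cronbach_alpha()`, never from the scoring itself. In typical
validation cohorts the single-parent, maternal-illicit-drug and inpatient
indicators never occur, which is exactly why they drop out of alpha — a
constant item carries no covariance information.

## Instrument schemas and scoring

Every battery instrument is described by a JSON schema: ordered item ids,
common per-item bounds, the reverse-keyed subset, and a subscale partition.
Scoring is uniformly "reflect reverse-keyed items (`lo + hi − v`), then
sum", with complete-case handling: a subscale sum is missing if any of its
items is, and the instrument total is missing if any item is. Reflection
is an involution and does not change attainable bounds, so the analytic
score range is simply `n_items × [lo, hi]` — which reproduces the
published ranges (PSS-14 0–56, ESI 0–60, HSCL-25 anxiety 10–40 and
depression 15–60, SCL-90-R somatization 0–48, PDS severity 0–51,
PSS-4 0–16).

Three schema choices are deliberately configurable rather than fixed,
because the underlying instruments do not pin them down for every
translation: the PSS-14 reverse-keyed set defaults to the standard
published seven positive items; the embedded PSS-4 defaults to the
standard four-item short form (two reverse-keyed); and the CFV per-subscale
item counts are **not authoritative** — the defaults (physical 9,
verbal-emotional 4, sexual 2, witnessed 3, neglect 2; binary items) were
chosen so each subscale's attainable maximum is at least the maxima
observed in published validation samples, and the schema file says so.
The PDS is scored as Part 1 event count (0–12) and Part 3 symptom
severity (0–51) only; Parts 2 and 4 feed no composite and are carried
verbatim.

## Global criterion composites

Criterion totals are z-transformed over the analysis cohort and summed
with unit weights:

- global stress = z(PSS-14) + z(ESI)
- global psychopathology = z(SCL somatization) + z(HSCL-25 anxiety +
  depression, standardized as one combined score) + z(PDS severity)
- global trauma load = z(PDS events) + z(CFV total)

The HSCL-25 enters as a single combined total (its two subscale sums are
still emitted for descriptive tables). Standardization constants come
from the complete cases of the cohort being analysed — composites are
cohort-relative, not norm-referenced — and the constants used are recorded
on the result. The default SD uses the sample (n−1) divisor, matching the
defaults of the statistics packages this analysis style comes from; a
population-SD switch exists because the choice is conventionally
underdetermined (it rescales each z-column by a constant and leaves rank
correlations unchanged). Missingness propagates per respondent: one
missing PDS severity scale makes global psychopathology (only) missing for
that respondent, reproducing the familiar N vs N−1 bookkeeping.

## Statistical battery

The analysis pipeline mirrors the nonparametric workflow of screening
validation studies: a normality gate followed by rank-based tests.

- **Normality gate.** Because the normal parameters are estimated from the
  data, the plain Kolmogorov–Smirnov p-values would be conservative; the
  Lilliefors-corrected test (`nortest::lillie.test`) is used and each
  variable is flagged at α = 0.05. The reported `n` is always the actual
  complete-case count for that variable.
- **Spearman rho** is computed as the product-moment correlation of
  midranks over pairwise-complete cases, with the two-sided
  t-approximation p-value on n−2 df. Constant margins yield an undefined
  rho, reported as `NA` rather than silently dropped.
- **Mann–Whitney U** reports both U values (they sum to `nA·nB`), uses
  midranks throughout, an exact enumeration p-value when the smaller group
  has ≤ 8 observations and there are no ties (enumeration capped at 5·10⁵
  assignments), and otherwise the tie-corrected normal approximation
  without continuity correction — the convention under which published U
  tables in this literature are computed. Group medians, minima and maxima
  accompany every comparison.
- **Kruskal–Wallis H** (tie-corrected, χ² reference on k−1 df),
  **pooled-variance t** (df = nA+nB−2), and **2×2 chi-square** without
  continuity correction (switchable) complete the battery. Two-sided
  p-values are the default everywhere; a one-sided option exists for the t
  test because some published interviewer comparisons are only consistent
  with a one-sided convention. No multiple-testing correction is applied —
  matching the analysis style this pipeline reproduces — and the report
  bundle counts the tests performed so a reader can apply their own.
- **Cronbach's alpha** is computed from the classical variance identity
  after excluding zero-variance items (the exclusions and reason are part
  of the result). There is no psychometrics dependency; the test suite
  cross-checks the implementation against the brute-force formula and the
  equicorrelated closed form `k·r̄ / (1 + (k−1)·r̄)`.

Degenerate inputs fail loudly and specifically: empty groups, both-groups
zero variance in the t test, zero margins in chi-square, constant input to
the normality test, and fewer than two usable items in alpha are all
errors naming the offending piece, never silent `NaN`s.

## The synthetic cohort model

`generate_cohort()` simulates what a screening study's data set looks
like: one latent adversity factor `A ~ N(0,1)` per respondent drives
everything that should covary.

- **Binary raw conditions** are `Bernoulli(logistic(α_i + λ_B·A))`. Each
  intercept `α_i` is calibrated by numerical integration
  (`calibrate_intercept()`, absolute error < 10⁻³) so the *marginal*
  prevalence hits its target regardless of the loading. Default targets
  follow the prevalence profile of a public-sector pregnant cohort
  (e.g. 24.4% lifetime psychiatric diagnosis, 11.8% childhood physical
  abuse, 54.6% physical complaints); three conditions are structurally
  zero (single parenthood, maternal illicit drugs, inpatient history) so
  the default conditions reproduce the 28-item reliability situation.
  The maternal smoking/alcohol defaults (16% / 1.7%) come from subgroup
  frequencies because the corresponding overall cells in the published
  table are internally inconsistent (the smoking row is formatted as a
  mean and the alcohol/smoking rows appear transposed); both are
  user-settable.
- **Ordinal ratings** (bonding joy/worries) are `round(mean + sd·(±λ_r·A +
  √(1−λ_r²)·ε))` clamped to 0–10, with means/SDs matching published
  descriptives (joy mother 7.66 ± 2.32, worries mother 6.02 ± 2.71, joy
  father 9.18 ± 1.52, worries father 5.28 ± 3.09). Joy loads negatively on
  adversity, worries positively.
- **Battery items** discretize a standard-normal item latent `λ_I·A +
  √(1−λ_I²)·ε` at fixed quantile thresholds, so the marginal category
  probabilities follow the configured threshold sets exactly whatever the
  loading. Default category probabilities were chosen once to give
  realistic low symptom endorsement (e.g. mean PSS-4 sum ≈ 3.7, mean PDS
  severity ≈ 3); they are per-instrument overridable. Reverse-keyed items
  are generated on the scored scale and stored raw, so schema scoring
  round-trips them.
- **Context fields** (age uniform-discrete 20–42, gestational week
  `N(31, 2.05)` clamped to the 24–36 eligibility window, hospital-unit and
  interviewer-profession mixes) reproduce typical recruitment structure
  but are independent of adversity; maternal age therefore contributes
  variance to the sum score without contributing to the latent coupling.
- **Missingness**: with probability 1/67 a respondent skips one random PDS
  symptom item — the typical "one stray missing value" pattern.

**Loading defaults.** The default loadings (binary λ_B = 0.47, instrument
items λ_I = 0.235, ratings λ_r = 0.19) were calibrated once, by large-n
simulation (n = 20 000), so that the population Spearman correlation
between the risk sum score and the global stress composite is ≈ 0.45 —
the concurrent-validity regime reported for instruments of this class.
They were then frozen; `loading_scale` multiplies all of them for
sensitivity analyses, and `calibrate_loadings()` re-derives the multiplier
for any other target regime by root-finding on simulated cohorts
(`uniroot`, multiplier tolerance 0.02, which maps to ≈ 0.01 on rho).

**What the generator does not emulate.** A single common factor cannot
produce domain-specific structure (e.g. trauma items correlating more with
each other than with stress items); real data would also show
informative missingness, interviewer effects, social-desirability
suppression of sensitive items (published IPV and sexual-abuse rates are
known underestimates), and ordinal rating distributions with spikes at 0,
5 and 10. Passing tests on synthetic cohorts therefore demonstrate that
the *pipeline* is correct and well-calibrated under a plausible
data-generating process — not that any substantive validity conclusion
transfers to real interviews.

## Reproducibility and problem sizes

Cohorts are bit-for-bit reproducible given `(config, seed)`. The recovery
experiment (`recovery_experiment()`) calibrates the loading multiplier,
then simulates replicate cohorts of the configured size (67 by default —
a typical validation subsample), scoring each through the full pipeline;
it reports the mean and SD of the estimated rho, Fisher-z 95% CI coverage
of the target, and the p ≤ 0.05 rejection rate. The suite runs it at 200
replicates for the rho = 0.45 regime and 1000 replicates for the null
(the null rejection rate is estimated with Monte Carlo SE ≈ 0.007, small
against its 0.03–0.07 calibration band). Prevalence convergence is
checked at n = 10⁴ (±2 percentage points), independence and coupling
properties at n = 8 000–20 000, and all statistical-engine oracles on
instances of n ≤ 10 against brute-force enumeration or closed forms.

## Known limitations

- The engine scores and analyses; it makes no clinical interpretation.
  The screening instrument itself is a referral aid, not a diagnostic
  tool, and this package implements nothing beyond the threshold flag.
- Sensitivity/specificity/ROC analysis is out of scope (it requires an
  external criterion diagnosis that a concurrent-validity design does not
  provide).
- CFV subscale composition and the exact PSS-4 item subset are
  configurable because they are genuinely underdetermined; results that
  depend on them should state the schema version used.
- The exact-U enumeration is limited to small untied samples; everything
  else uses the tie-corrected normal approximation, which is the matching
  convention for published tables but is approximate for very small tied
  samples.
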