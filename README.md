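# kindexr

Scoring engine and concurrent-validity analysis for the **KINDEX**
(Konstanz INDEX), a short structured prenatal interview that lets midwives
and gynecologists screen pregnant women for psychosocial risk factors —
maternal stress, mental-health history, intimate partner violence,
childhood maltreatment, substance use, financial strain, migration
background, young maternal age, medical risks and poor prenatal bonding —
without any training in psychosocial concepts. The package is aimed at
researchers validating or adapting screening instruments of this kind, and
at analysts who need a reproducible implementation of the scoring rules.

## What it computes

**Risk scoring.** The interview yields 31 dichotomous risk indicators
grouped into 11 risk areas. Ordinal answers are dichotomized by fixed
recode rules: maternal age ≤ 21; bonding ratings at the extreme quartiles
(joy 0–3, worries 7–10 on 0–10 scales); an embedded 4-item Perceived
Stress Scale (PSS-4, range 0–16) cut at its upper quartile (sum ≥ 12); and
a household crowding index flagged when rooms/persons ≤ 0.5. The risk sum
score is the count of positive indicators (0–31); a referral flag marks
respondents with 2 or more risks.

**Criterion battery.** Declarative JSON schemas score the validation
instruments — PSS-14 (0–56, seven reverse-keyed items), Everyday Stressors
Index (0–60), Hopkins Symptom Checklist-25 (anxiety 10–40, depression
15–60), SCL-90-R somatization (0–48), the Posttraumatic Stress Diagnostic
Scale event checklist (0–12) and symptom severity (0–51), and the
Checklist of Family Violence — all as "sum after reverse coding" with
complete-case missing handling. Three z-based criterion composites are
built per cohort:

    global stress          = z(PSS-14) + z(ESI)
    global psychopathology = z(SCL somatization) + z(HSCL-25 total) + z(PDS severity)
    global trauma load     = z(PDS event count) + z(CFV total)

**Statistics.** Cronbach's alpha with zero-variance item exclusion,
Lilliefors (Kolmogorov–Smirnov) normality screening, Spearman rank
correlations, Mann–Whitney U (exact for small untied samples, tie-corrected
normal approximation otherwise), Kruskal–Wallis H, pooled-variance t, and
2×2 chi-square tests, assembled by `run_validation_pipeline()` into a
report bundle with descriptive, correlation and item-criterion tables.

**Synthetic cohorts.** A single-latent-factor generator simulates raw
interviews plus battery item responses with realistic indicator
prevalences and a controllable coupling between the risk score and the
criterion composites, so the whole pipeline can be exercised, calibrated
and power-checked without any real respondent data.

## Worked example

```r
library(kindexr)

cohort <- generate_cohort(generator_config(n = 119, seed = 1,
                                           n_validation = 67))
report <- run_validation_pipeline(cohort)
report
#> <kindex_report> n = 119, battery n = 67
#>   reliability: alpha = 0.344 (25 items retained)
#>   correlations (sum score vs composites):
#> # A tibble: 3 × 5
#>   var1      var2                     rho     n       p
#>   <chr>     <chr>                  <dbl> <int>   <dbl>
#> 1 sum_score global_stress          0.358    67 0.00291
#> 2 sum_score global_psychopathology 0.358    67 0.00298
#> 3 sum_score global_trauma_load     0.266    67 0.0296
#>   53 significance tests performed (no multiplicity correction)
```

The simulated cohort of 119 interviews (67 with the full battery) shows
the behaviour expected at study scale: the risk sum score correlates
positively with all three criterion composites (here rho ≈ 0.27–0.36 — a
single n = 67 draw from a generator whose population coupling is
calibrated to rho ≈ 0.45), and several very rare indicators happen to be
constant in this draw, so the zero-variance filter retains 25 of the 31
items before computing alpha. At the generator's default conditions the
structurally absent indicators (single parenthood, maternal illicit drug
use, inpatient psychiatric history) are always excluded.

```r
prof <- risk_profile(cohort$interviews)
mean(prof$sum_score)     #> 4.57   average number of risks per respondent
mean(prof$referral_flag) #> 0.95   share with >= 2 risks (referral rule)
```

A ready-made command-line wrapper is installed at
`inst/scripts/kindex.R` (`simulate`, `score`, `report` subcommands).

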