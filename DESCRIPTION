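Package: kindexr
Title: Scoring and Concurrent-Validity Analysis for the KINDEX Prenatal
    Psychosocial Risk Screening Interview
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the KINDEX (Konstanz INDEX) prenatal psychosocial
    risk screening interview as a scoring engine: derivation of the 31
    dichotomous risk indicators across 11 risk areas, the risk sum score
    and the referral flag. Also provides declarative schemas and scoring
    for the standardized instruments of a concurrent-validity battery
    (PSS-4/PSS-14, ESI, HSCL-25, SCL-90-R somatization, PDS, CFV),
    z-standardized global criterion composites, the nonparametric
    statistical battery used in screening validation studies (Spearman
    rank correlations, Mann-Whitney U, Kruskal-Wallis H, chi-square,
    Lilliefors normality screening, Cronbach's alpha with zero-variance
    item exclusion), and a latent-trait synthetic cohort generator so the
    full analysis pipeline can be exercised and calibrated without raw
    interview data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    nortest,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
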