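Package: tapscore
Title: Scoring Engine for Rhythm and Tempo Tapping Reproduction Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores finger-tapped reproductions of rhythmic and isochronous
    (tempo) patterns against normative inter-onset-interval series. Classifies
    reproductions as structurally correct or incorrect by nearest-note-value
    assignment of each inter-tap interval, run in parallel on absolute
    (millisecond) and relative (tempo-invariant, 0-1 rescaled) interval
    streams; rejects outlier reproductions with cohort-level Tukey fences at
    3 x IQR; and quantifies temporal accuracy as mean percent deviation of
    cumulative tap times from cumulative reference onsets. Includes
    participant-level aggregation with exclusion rules, confidence-weighted
    perception-item scoring, reliability machinery (item-mean imputation,
    McDonald's omega from a single-factor minimum-residual fit, intraclass
    and Spearman test-retest correlations), and a seeded synthetic-cohort
    simulator with motor jitter, global tempo scaling, structural errors and
    rare outlier intervals for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
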