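Package: utitrack
Title: Mouse-Tracking Classification Task Analysis for the Unhealthy = Tasty Intuition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis toolkit for a two-choice mouse-tracking food
    classification task that yields a process-based behavioral index of the
    "unhealthy = tasty" intuition (UTI). Reads long-format cursor logs, trial
    and participant tables; remaps, mirrors and resamples cursor trajectories;
    computes trial-level conflict metrics (reaction time, signed maximum
    absolute deviation, sample entropy); aggregates them into participant-level
    difference-score indices with preregistered-style outlier exclusion; scores
    the explicit UTI scale and a food-frequency diet quality score; and fits the
    validation statistics (correlations, Welch tests, crossed random-intercept
    mixed models, simple-slope contrasts, incremental-validity model
    comparisons, Fisher-z power analysis). Includes a synthetic-cohort
    simulator with known latent-trait ground truth so every stage of the
    pipeline can be tested without collected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr
Config/testthat/edition: 3
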