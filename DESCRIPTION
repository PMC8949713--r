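Package: boutscan
Title: Physical Activity Bout Patterns from Minute-Epoch Accelerometry in
    Rehabilitation Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives physical activity pattern outcomes from minute-epoch
    accelerometer exports (MET-per-minute, steps) for two-arm pre/post
    rehabilitation trials: wear-time validity filtering (>=8 wear-hours per
    day on >=4 days), MET-based intensity classification (light >1.5,
    moderate 3-6, vigorous >6 METs), detection of maximal
    moderate-to-vigorous activity bouts and their accumulation spectrum at
    configurable duration thresholds (2, 5, 10, 20 minutes), per-participant
    activity summaries, and the trial statistics layer (paired and
    independent t tests, two-way mixed-design repeated-measures ANOVA,
    tie-aware Spearman correlation). Includes a synthetic minute-epoch
    cohort simulator with planted wear patterns, geometric bout-length
    distributions and arm-specific intervention effects, with a
    planted-truth ledger for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
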