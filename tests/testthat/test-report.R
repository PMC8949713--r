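toy_cohort <- function(web_base, web_dis, conv_base, conv_dis, metric = "steps_per_day") {
  row <- function(id, arm, tp, v) {
    out <- tibble::tibble(participant_id = id, arm = arm, timepoint = tp)
    out[[metric]] <- v
    out
  }
  dplyr::bind_rows(
    purrr::imap(web_base, \(v, i) row(paste0("W", i), "web", "baseline", v)),
    purrr::imap(web_dis, \(v, i) row(paste0("W", i), "web", "discharge", v)),
    purrr::imap(conv_base, \(v, i) row(paste0("C", i), "conventional", "baseline", v)),
    purrr::imap(conv_dis, \(v, i) row(paste0("C", i), "conventional", "discharge", v))
  )
}

test_that("group cells are means/SDs and single-participant SDs are flagged", {
  cohort <- toy_cohort(4000, 5000, 6000, 6600)
  gs <- build_group_summary(cohort, metrics = "steps_per_day")
  web <- gs[gs$arm == "web", ]
  expect_equal(web$baseline_mean, 4000)
  expect_true(is.na(web$baseline_sd))
  expect_equal(web$n_baseline, 1L)
  expect_equal(web$pct_change, 25)
})

test_that("percent change on group means reproduces the published step cells", {
  cohort <- toy_cohort(c(5464.6 - 500, 5464.6 + 500), c(6111.7 - 400, 6111.7 + 400),
                       c(5300.1 - 300, 5300.1 + 300), c(5409.4 - 200, 5409.4 + 200))
  gs <- build_group_summary(cohort, metrics = "steps_per_day")
  expect_equal(round(gs$pct_change[gs$arm == "web"]), 12)
  expect_equal(round(gs$abs_change[gs$arm == "web"]), 647)
  expect_equal(round(gs$pct_change[gs$arm == "conventional"]), 2)
})

test_that("group summaries are permutation-invariant", {
  set.seed(51)
  cohort <- toy_cohort(rnorm(5, 5000, 800), rnorm(5, 5500, 800),
                       rnorm(8, 5200, 900), rnorm(8, 5250, 900))
  a <- build_group_summary(cohort, metrics = "steps_per_day")
  b <- build_group_summary(cohort[sample(nrow(cohort)), ], metrics = "steps_per_day")
  expect_equal(a, b)
})

test_that("the pipeline writes consistent, recomputable, deterministic outputs", {
  sim <- simulate_cohort(n_web = 3, n_conventional = 4, n_days = 5, seed = 52)
  d1 <- withr::local_tempdir()
  res <- run_pipeline(sim$epochs, sim$manifest, out_dir = d1)
  expect_true(all(file.exists(unlist(res$paths))))

  # every group_summary number is recomputable from participant_summaries
  ps <- readr::read_csv(res$paths$participant_summaries, show_col_types = FALSE)
  gs <- readr::read_csv(res$paths$group_summary, show_col_types = FALSE)
  manifest <- sim$manifest[, c("participant_id", "arm")]
  ps <- dplyr::left_join(ps, manifest, by = "participant_id")
  for (i in seq_len(nrow(gs))) {
    v <- ps[[gs$metric[i]]][ps$arm == gs$arm[i] & ps$timepoint == "baseline"]
    expect_equal(gs$baseline_mean[i], mean(v), tolerance = 1e-12)
    if (length(v) >= 2) expect_equal(gs$baseline_sd[i], sd(v), tolerance = 1e-12)
  }

  # exclusions in the log line up with the planted invalid-day bookkeeping
  truth_valid <- sim$truth$days |>
    dplyr::group_by(participant_id, timepoint) |>
    dplyr::summarise(n_valid = sum(planted_valid), .groups = "drop")
  expected_excluded <- truth_valid[truth_valid$n_valid < 4, ]
  got_excluded <- res$validity[!res$validity$included, ]
  expect_equal(sort(paste(got_excluded$participant_id, got_excluded$timepoint)),
               sort(paste(expected_excluded$participant_id, expected_excluded$timepoint)))

  # rerun on identical inputs is byte-identical
  d2 <- withr::local_tempdir()
  run_pipeline(sim$epochs, sim$manifest, out_dir = d2)
  for (f in c("participant_summaries.csv", "group_summary.csv", "stats.csv", "run_log.txt")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  # the run log reports the test count alongside alpha
  expect_true(any(grepl("significance tests performed: \\d+ at alpha", readLines(res$paths$run_log))))
})

test_that("configured bout thresholds drive the summary columns", {
  sim <- simulate_cohort(n_web = 2, n_conventional = 2, n_days = 4, seed = 53)
  d <- withr::local_tempdir()
  res <- run_pipeline(sim$epochs, sim$manifest, out_dir = d,
                      duration_thresholds = c(2, 5))
  bout_cols <- grep("^bouts_", names(res$participant_summaries), value = TRUE)
  expect_equal(bout_cols, c("bouts_2", "bouts_5"))
  expect_setequal(unique(res$group_summary$metric),
                  c("steps_per_day", "daily_mets", "pct_time_moderate",
                    "mean_bout_length_min", "bouts_2", "bouts_5", "total_mvpa_min"))
})
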