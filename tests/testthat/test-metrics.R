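make_valid_days <- function(steps, moderate = 60, wear = 600, mets_mean = 1.5,
                            participant_id = "P01", timepoint = "baseline") {
  n <- length(steps)
  tibble::tibble(
    participant_id = participant_id, timepoint = timepoint,
    date = as.Date("2019-01-07") + seq_len(n) - 1,
    wear_minutes = as.integer(wear), valid = TRUE, steps = as.integer(steps),
    met_minutes = mets_mean * wear,
    min_sedentary_or_below = as.integer(wear - moderate - 100),
    min_light = 100L, min_moderate = as.integer(moderate), min_vigorous = 0L
  )
}

test_that("participant summaries are day means and pooled wear-weighted rates", {
  days <- make_valid_days(c(4000, 6000, 5000, 5000))
  sp <- bout_spectrum(tibble::tibble(duration_min = c(2, 2, 5, 11, 21)), 4)
  s <- summarize_participant(days, sp)
  expect_equal(s$steps_per_day, 5000)
  expect_equal(s$daily_mets, 1.5)
  expect_equal(s$pct_time_moderate, 100 * 60 / 600)
  expect_equal(s$mean_bout_length_min, mean(c(2, 2, 5, 11, 21)))
  expect_equal(s$bouts_2, 5 / 4)
  expect_equal(s$bouts_20, 1 / 4)
  expect_equal(s$total_mvpa_min, sum(c(2, 2, 5, 11, 21)) / 4)
})

test_that("an all-resting participant has 1.0 daily METs and no moderate time", {
  days <- make_valid_days(rep(0, 4), moderate = 0, mets_mean = 1.0)
  days$min_light <- 0L
  days$min_sedentary_or_below <- days$wear_minutes
  s <- summarize_participant(days, bout_spectrum(tibble::tibble(duration_min = integer()), 4))
  expect_equal(s$daily_mets, 1.0)
  expect_equal(s$pct_time_moderate, 0)
})

test_that("too few valid days is a refusal naming the reason", {
  days <- make_valid_days(c(1000, 2000, 3000))
  sp <- bout_spectrum(tibble::tibble(duration_min = integer()), 3)
  expect_error(summarize_participant(days, sp), "too few valid days: 3")
})

test_that("summaries are order-invariant and scale in steps only", {
  days <- make_valid_days(c(3000, 8000, 4000, 6000, 2000))
  sp <- bout_spectrum(tibble::tibble(duration_min = c(3, 6)), 5)
  a <- summarize_participant(days, sp)
  b <- summarize_participant(days[sample(5), ], sp)
  expect_equal(a, b)

  doubled <- days
  doubled$steps <- doubled$steps * 2L
  d <- summarize_participant(doubled, sp)
  expect_equal(d$steps_per_day, 2 * a$steps_per_day)
  expect_equal(d[setdiff(names(d), "steps_per_day")],
               a[setdiff(names(a), "steps_per_day")])
})

test_that("percent change matches the published step-change arithmetic", {
  expect_equal(round(percent_change(5464.6, 6111.7), 1), 11.8)
  expect_equal(round(percent_change(5464.6, 6111.7)), 12)
  expect_equal(round(percent_change(5300.1, 5409.4), 1), 2.1)
  expect_equal(round(percent_change(5300.1, 5409.4)), 2)
  expect_equal(percent_change(1234.5, 1234.5), 0)
  expect_error(percent_change(0, 10), "non-positive")
  expect_error(percent_change(-5, 10), "non-positive")
})

test_that("a simulated participant's planted rates are recovered", {
  prof <- activity_profile(p_invalid_day = 0)
  set.seed(606)
  n_days <- 40
  days <- list(); bouts <- list()
  for (d in seq_len(n_days)) {
    sim <- simulate_participant_day(prof, date = as.Date("2019-01-07") + d - 1)
    days[[d]] <- summarize_day(sim$epochs)
    bouts[[d]] <- detect_bouts(sim$epochs)
  }
  days <- dplyr::bind_rows(days)
  bouts <- dplyr::bind_rows(bouts)
  s <- summarize_participant(days, bout_spectrum(bouts, n_days))

  # detected MVPA equals planted MVPA day by day (ledger conservation is
  # exercised in the simulator tests); here check the pooled summaries sit
  # within 3 Monte-Carlo SEs of the planted expectations
  exp_steps <- with(prof, mvpa_bout_rate / bout_length_p * steps_per_mvpa_min +
                      light_rate * steps_per_light_min)
  se_steps <- sd(days$steps) / sqrt(n_days)
  expect_lt(abs(s$steps_per_day - exp_steps), 3 * se_steps + 1e-9)

  exp_len <- 1 / prof$bout_length_p
  se_len <- sd(bouts$duration_min) / sqrt(nrow(bouts))
  expect_lt(abs(s$mean_bout_length_min - exp_len), 3 * se_len)
})
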