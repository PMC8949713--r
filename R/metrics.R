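#' Per-participant activity summary at one timepoint
#'
#' Collapses the valid days of one participant-timepoint into the standard
#' activity-pattern row: mean steps per valid day; daily MET level (the
#' worn-minute MET mean pooled across valid days); percentage of wear time
#' in the moderate class (moderate only, not MVPA); and the bout fields of
#' the supplied [bout_spectrum()] (mean bout length, bouts per day at each
#' duration threshold, total MVPA minutes per day).
#'
#' @param valid_days day summaries ([summarize_days()]) restricted to this
#'   participant-timepoint's valid days.
#' @param spectrum a [bout_spectrum()] computed over the same valid days.
#' @param criteria the [wear_criteria()] in force; supplying fewer valid
#'   days than `criteria$min_valid_days` is an error naming the reason.
#'
#' @return One-row tibble: ids, `n_valid_days`, `steps_per_day`,
#'   `daily_mets`, `pct_time_moderate`, `mean_bout_length_min`, one
#'   `bouts_<d>` column per spectrum threshold, `total_mvpa_min`.
#' @export
summarize_participant <- function(valid_days, spectrum,
                                  criteria = wear_criteria()) {
  stopifnot(inherits(spectrum, "bout_spectrum"), inherits(criteria, "wear_criteria"))
  n <- nrow(valid_days)
  if (n < criteria$min_valid_days) {
    abort(paste0("participant-timepoint failed wear validity: too few valid days: ", n))
  }
  if (length(unique(valid_days$participant_id)) != 1L ||
      length(unique(valid_days$timepoint)) != 1L) {
    abort("valid_days must come from a single participant-timepoint")
  }
  wear <- sum(valid_days$wear_minutes)
  out <- tibble(
    participant_id = valid_days$participant_id[1],
    timepoint = valid_days$timepoint[1],
    n_valid_days = n,
    steps_per_day = mean(valid_days$steps),
    daily_mets = sum(valid_days$met_minutes) / wear,
    pct_time_moderate = 100 * sum(valid_days$min_moderate) / wear,
    mean_bout_length_min = spectrum$mean_bout_length_min
  )
  for (d in names(spectrum$counts_per_day)) {
    out[[paste0("bouts_", d)]] <- spectrum$counts_per_day[[d]]
  }
  out$total_mvpa_min <- spectrum$total_mvpa_min
  out
}

#' Percent change between two positive measurements
#'
#' `100 * (discharge - baseline) / baseline`. Undefined (an error) when the
#' baseline is not strictly positive. Rounding to the integer or one
#' decimal is left to the reporting layer.
#'
#' @param baseline,discharge numeric vectors (recycled as usual).
#' @return Numeric vector of percent changes.
#' @export
#' @examples
#' percent_change(5464.6, 6111.7)  # 11.84 -> reported "12%"
percent_change <- function(baseline, discharge) {
  if (any(!is.finite(baseline)) || any(baseline <= 0)) {
    abort("percent change is undefined for non-positive baseline")
  }
  100 * (discharge - baseline) / baseline
}

#' Full participant-level summarisation of an epoch table
#'
#' Runs wear summarisation, the validity filter, bout detection over valid
#' days and [summarize_participant()] for every included
#' participant-timepoint.
#'
#' @param epochs epoch tibble.
#' @param thresholds an [intensity_thresholds()] object.
#' @param criteria a [wear_criteria()] object.
#' @param duration_thresholds bout duration thresholds in minutes.
#' @param max_break_min bout interruption tolerance (see [detect_bouts()]).
#'
#' @return List with `participant_summaries` (one row per included
#'   participant-timepoint), `day_summaries`, `validity` (the
#'   [select_valid_participants()] table) and `bouts` (all detected bouts
#'   on valid days).
#' @export
summarize_cohort <- function(epochs, thresholds = intensity_thresholds(),
                             criteria = wear_criteria(),
                             duration_thresholds = c(2, 5, 10, 20),
                             max_break_min = 0) {
  days <- summarize_days(epochs, thresholds, criteria$min_wear_minutes_per_day)
  validity <- select_valid_participants(days, criteria)
  included <- validity[validity$included, c("participant_id", "timepoint")]

  epochs <- mutate(epochs, date = as.Date(.data$timestamp, tz = "UTC"))
  valid_days_tbl <- days |>
    mutate(valid = .data$wear_minutes >= criteria$min_wear_minutes_per_day) |>
    filter(.data$valid)

  summaries <- list()
  all_bouts <- list()
  for (i in seq_len(nrow(included))) {
    pid <- included$participant_id[i]
    tp <- included$timepoint[i]
    vd <- valid_days_tbl |> filter(.data$participant_id == pid, .data$timepoint == tp)
    ep <- epochs |> filter(.data$participant_id == pid,
                           as.character(.data$timepoint) == tp,
                           .data$date %in% vd$date)
    bouts <- ep |>
      group_by(.data$date) |>
      dplyr::group_split() |>
      lapply(detect_bouts, thresholds = thresholds, max_break_min = max_break_min) |>
      bind_rows()
    spec <- bout_spectrum(bouts, nrow(vd), duration_thresholds)
    summaries[[i]] <- summarize_participant(vd, spec, criteria)
    if (nrow(bouts)) all_bouts[[length(all_bouts) + 1L]] <- bouts
  }
  list(
    participant_summaries = bind_rows(summaries),
    day_summaries = days,
    validity = validity,
    bouts = bind_rows(all_bouts)
  )
}
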