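#' Wear-time validity criteria
#'
#' A calendar day is valid when the device was worn for at least
#' `min_wear_minutes_per_day` minutes (default 480, i.e. 8 hours), and a
#' participant-timepoint enters analysis when it has at least
#' `min_valid_days` valid days (default 4). Validity is assessed per
#' timepoint: a participant can be valid at baseline and not at discharge.
#'
#' @param min_wear_minutes_per_day positive integer, minimum worn minutes
#'   for a valid day.
#' @param min_valid_days positive integer, minimum number of valid days for
#'   an analysable participant-timepoint.
#'
#' @return An object of class `wear_criteria`.
#' @export
wear_criteria <- function(min_wear_minutes_per_day = 480L, min_valid_days = 4L) {
  if (min_wear_minutes_per_day < 1 || min_valid_days < 1) {
    abort("wear criteria must be strictly positive")
  }
  structure(
    list(min_wear_minutes_per_day = as.integer(min_wear_minutes_per_day),
         min_valid_days = as.integer(min_valid_days)),
    class = "wear_criteria"
  )
}

#' Summarise one participant-day of epochs
#'
#' Counts worn minutes, steps, the MET-minute total, and the partition of
#' worn minutes across intensity classes for a single participant-day.
#' Non-worn epochs contribute to nothing. An empty day yields zero wear and
#' `valid = FALSE`.
#'
#' @param epochs data frame of minute epochs for one participant-day
#'   (columns `participant_id`, `timepoint`, `timestamp`, `mets`, `steps`,
#'   `worn`).
#' @param thresholds an [intensity_thresholds()] object.
#' @param min_wear_minutes minimum worn minutes for the day to be valid
#'   (default 480).
#'
#' @return One-row tibble: ids, `date`, `wear_minutes`, `valid`, `steps`,
#'   `met_minutes` (sum of METs over worn minutes, for pooled daily-MET
#'   means) and `min_sedentary_or_below`/`min_light`/`min_moderate`/
#'   `min_vigorous`.
#' @export
summarize_day <- function(epochs, thresholds = intensity_thresholds(),
                          min_wear_minutes = 480L) {
  if (nrow(epochs) == 0L) {
    return(tibble(
      participant_id = NA_character_, timepoint = NA_character_,
      date = as.Date(NA), wear_minutes = 0L, valid = FALSE, steps = 0L,
      met_minutes = 0, min_sedentary_or_below = 0L, min_light = 0L,
      min_moderate = 0L, min_vigorous = 0L
    ))
  }
  dates <- unique(as.Date(epochs$timestamp, tz = "UTC"))
  if (length(dates) > 1L || length(unique(epochs$participant_id)) > 1L) {
    abort("summarize_day() expects epochs from a single participant-day")
  }
  worn <- epochs$worn
  cls <- classify_epoch(epochs$mets, thresholds)
  tab <- table(factor(cls[worn], levels = INTENSITY_LEVELS))
  wear <- sum(worn)
  tibble(
    participant_id = as.character(epochs$participant_id[1]),
    timepoint = as.character(epochs$timepoint[1]),
    date = dates,
    wear_minutes = as.integer(wear),
    valid = wear >= min_wear_minutes,
    steps = as.integer(sum(epochs$steps[worn])),
    met_minutes = sum(epochs$mets[worn]),
    min_sedentary_or_below = as.integer(tab[["sedentary_or_below"]]),
    min_light = as.integer(tab[["light"]]),
    min_moderate = as.integer(tab[["moderate"]]),
    min_vigorous = as.integer(tab[["vigorous"]])
  )
}

#' Summarise every participant-day in an epoch table
#'
#' @param epochs epoch tibble as returned by [read_epoch_csv()] or
#'   [simulate_cohort()].
#' @inheritParams summarize_day
#' @return Tibble of day summaries, one row per participant-timepoint-day.
#' @export
summarize_days <- function(epochs, thresholds = intensity_thresholds(),
                           min_wear_minutes = 480L) {
  epochs |>
    mutate(.date = as.Date(.data$timestamp, tz = "UTC")) |>
    group_by(.data$participant_id, .data$timepoint, .data$.date) |>
    group_modify_days(thresholds, min_wear_minutes)
}

group_modify_days <- function(grouped, thresholds, min_wear_minutes) {
  parts <- dplyr::group_split(grouped)
  bind_rows(lapply(parts, function(d) {
    summarize_day(dplyr::select(d, -".date"), thresholds, min_wear_minutes)
  }))
}

#' Apply the validity filter to day summaries
#'
#' A participant-timepoint is included iff its number of valid days (worn
#' minutes at or above the daily criterion) reaches `min_valid_days`.
#' Exclusions carry a reason string. Day `valid` flags are recomputed from
#' `wear_minutes` against the supplied criteria, so the decision depends
#' only on wear minutes, never on how days were ordered or on non-worn
#' epochs.
#'
#' @param day_summaries tibble from [summarize_days()].
#' @param criteria a [wear_criteria()] object.
#'
#' @return Tibble with one row per participant-timepoint: `n_days`,
#'   `n_valid_days`, `included` (logical), `reason` (`NA` when included,
#'   else e.g. `"too few valid days: 3"`).
#' @export
select_valid_participants <- function(day_summaries, criteria = wear_criteria()) {
  stopifnot(inherits(criteria, "wear_criteria"))
  day_summaries |>
    mutate(valid = .data$wear_minutes >= criteria$min_wear_minutes_per_day) |>
    group_by(.data$participant_id, .data$timepoint) |>
    summarise(
      n_days = dplyr::n(),
      n_valid_days = sum(.data$valid),
      .groups = "drop"
    ) |>
    mutate(
      included = .data$n_valid_days >= criteria$min_valid_days,
      reason = ifelse(.data$included, NA_character_,
                      paste0("too few valid days: ", .data$n_valid_days))
    )
}
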