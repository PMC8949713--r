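#' MET intensity thresholds
#'
#' Cut-points (in METs, multiples of resting oxygen consumption) separating
#' the four intensity classes used throughout the package. The defaults are
#' the SenseWear-style conventions for adults: light activity is anything
#' strictly above 1.5 METs, moderate is the closed band \[3, 6\] METs, and
#' vigorous is strictly above 6 METs. Note the boundary reading: exactly
#' 6.0 METs is moderate, not vigorous, and exactly 1.5 METs is sedentary.
#'
#' @param light_min exclusive lower MET bound of the light class (default 1.5).
#' @param moderate_min inclusive lower MET bound of the moderate class (default 3).
#' @param moderate_max inclusive upper MET bound of the moderate class (default 6).
#' @param vigorous_min exclusive lower MET bound of the vigorous class
#'   (default 6; must equal `moderate_max` unless a deliberate gap is wanted).
#'
#' @return An object of class `intensity_thresholds`.
#' @export
#' @examples
#' th <- intensity_thresholds()
#' classify_epoch(c(0, 1.5, 1.51, 3, 6, 6.01), th)
intensity_thresholds <- function(light_min = 1.5, moderate_min = 3,
                                 moderate_max = 6, vigorous_min = 6) {
  for (v in c(light_min, moderate_min, moderate_max, vigorous_min)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      abort("intensity thresholds must be single non-missing numbers")
    }
  }
  if (!(light_min < moderate_min && moderate_min <= moderate_max &&
        moderate_max <= vigorous_min)) {
    abort("thresholds must satisfy light_min < moderate_min <= moderate_max <= vigorous_min")
  }
  structure(
    list(light_min = light_min, moderate_min = moderate_min,
         moderate_max = moderate_max, vigorous_min = vigorous_min),
    class = "intensity_thresholds"
  )
}

#' Classify epochs by MET intensity
#'
#' Maps MET values to the four-class intensity scale: vigorous iff
#' `mets > vigorous_min`, moderate iff `moderate_min <= mets <= moderate_max`,
#' light iff `light_min < mets < moderate_min`, else sedentary-or-below.
#' `NA` METs (non-worn epochs) classify to `NA`.
#'
#' @param mets numeric vector of non-negative MET values (`NA` allowed).
#' @param thresholds an [intensity_thresholds()] object.
#'
#' @return A factor with levels
#'   `c("sedentary_or_below", "light", "moderate", "vigorous")`.
#' @export
classify_epoch <- function(mets, thresholds = intensity_thresholds()) {
  stopifnot(inherits(thresholds, "intensity_thresholds"))
  if (any(mets < 0, na.rm = TRUE)) {
    abort("MET values must be non-negative")
  }
  cls <- rep(NA_character_, length(mets))
  ok <- !is.na(mets)
  m <- mets[ok]
  out <- rep("sedentary_or_below", length(m))
  out[m > thresholds$light_min & m < thresholds$moderate_min] <- "light"
  out[m >= thresholds$moderate_min & m <= thresholds$moderate_max] <- "moderate"
  out[m > thresholds$vigorous_min] <- "vigorous"
  cls[ok] <- out
  factor(cls, levels = INTENSITY_LEVELS)
}

#' Detect MVPA bouts in one participant-day
#'
#' A bout is a maximal run of consecutive worn minutes at
#' moderate-to-vigorous intensity (MVPA, METs at or above the moderate
#' cut-point; vigorous minutes do not break a bout). A missing minute
#' (timestamp gap) or a non-worn minute always ends a run. Runs of length 1
#' are retained as 1-minute bouts: they contribute to mean bout length and
#' total MVPA but to no duration-threshold count of 2 minutes or more.
#'
#' With `max_break_min > 0`, two runs separated by at most that many
#' consecutive worn sub-moderate minutes are merged into one bout; the bout
#' duration and mean METs still count MVPA minutes only. The default of 0
#' (no interruption tolerance) is the strict convention used for all
#' headline outputs.
#'
#' @param epochs a data frame for a single participant-day with columns
#'   `timestamp` (POSIXct, strictly increasing, 1-minute grid), `mets`, and
#'   `worn` (logical).
#' @param thresholds an [intensity_thresholds()] object.
#' @param max_break_min non-negative integer interruption tolerance in minutes.
#'
#' @return A tibble with one row per bout: `start` (POSIXct), `duration_min`
#'   (MVPA minutes in the bout) and `mean_mets` (mean over MVPA minutes).
#'   Carries `participant_id`/`timepoint` columns when present in `epochs`.
#' @export
#' @examples
#' day <- tibble::tibble(
#'   timestamp = as.POSIXct("2019-01-07 09:00", tz = "UTC") + 60 * (0:7),
#'   mets = c(2, 4, 4, 2, 4, 4, 4, 2),
#'   worn = TRUE
#' )
#' detect_bouts(day)$duration_min  # 2, 3
detect_bouts <- function(epochs, thresholds = intensity_thresholds(),
                         max_break_min = 0) {
  stopifnot(is.data.frame(epochs))
  if (max_break_min < 0) abort("max_break_min must be non-negative")
  empty <- tibble(
    participant_id = character(), timepoint = character(),
    start = as.POSIXct(character(), tz = "UTC"),
    duration_min = integer(), mean_mets = double()
  )
  if (nrow(epochs) == 0L) return(empty)
  ts <- epochs$timestamp
  if (length(unique(as.Date(ts, tz = "UTC"))) > 1L) {
    abort("detect_bouts() expects epochs from a single calendar day")
  }
  dmin <- as.numeric(diff(ts), units = "mins")
  if (any(dmin <= 0)) {
    abort("epochs must be strictly time-ordered with no duplicate minutes")
  }

  worn <- epochs$worn
  cls <- classify_epoch(epochs$mets, thresholds)
  mvpa <- !is.na(cls) & worn & cls %in% c("moderate", "vigorous")

  # run id increments at timestamp gaps (> 1 min) and at non-worn minutes;
  # both are hard breaks even under an interruption tolerance
  brk <- cumsum(c(0, dmin != 1) + as.integer(!worn))
  brk[!worn] <- NA  # non-worn epochs belong to no run

  bouts <- list()
  idx <- seq_along(ts)
  for (b in unique(brk[!is.na(brk)])) {
    sel <- idx[!is.na(brk) & brk == b]
    r <- rle(mvpa[sel])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = sel[starts], end = sel[ends], mvpa = r$values)
    act <- runs[runs$mvpa, , drop = FALSE]
    if (nrow(act) == 0L) next
    if (max_break_min > 0 && nrow(act) > 1L) {
      # merge MVPA runs split by short worn sub-moderate interruptions
      merged <- act[1, , drop = FALSE]
      for (k in 2:nrow(act)) {
        gap <- act$start[k] - merged$end[nrow(merged)] - 1L
        if (gap <= max_break_min) {
          merged$end[nrow(merged)] <- act$end[k]
        } else {
          merged <- rbind(merged, act[k, , drop = FALSE])
        }
      }
      act <- merged
    }
    for (k in seq_len(nrow(act))) {
      span <- act$start[k]:act$end[k]
      span <- span[mvpa[span]]
      bouts[[length(bouts) + 1L]] <- tibble(
        start = ts[span[1]],
        duration_min = length(span),
        mean_mets = mean(epochs$mets[span])
      )
    }
  }
  if (length(bouts) == 0L) {
    out <- empty
  } else {
    out <- bind_rows(bouts)
    out <- out[order(out$start), , drop = FALSE]
    out$participant_id <- if ("participant_id" %in% names(epochs)) epochs$participant_id[1] else NA_character_
    out$timepoint <- if ("timepoint" %in% names(epochs)) as.character(epochs$timepoint[1]) else NA_character_
  }
  out[, c("participant_id", "timepoint", "start", "duration_min", "mean_mets")]
}

#' Bout-accumulation spectrum over valid days
#'
#' Summarises detected bouts across the valid days of one
#' participant-timepoint: for every duration threshold d, the mean number of
#' bouts per valid day lasting at least d minutes, plus the pooled mean bout
#' length and total MVPA minutes per valid day. The spectrum is by
#' construction non-increasing in the duration threshold, and the sum of
#' bout durations is conserved as `total_mvpa_min * n_valid_days`.
#'
#' @param bouts tibble of bouts as from [detect_bouts()], pooled over the
#'   valid days (may have zero rows).
#' @param n_valid_days number of valid days the bouts were pooled over
#'   (must be at least 1).
#' @param duration_thresholds integer vector of minimum bout durations in
#'   minutes (default `c(2, 5, 10, 20)`).
#'
#' @return A list of class `bout_spectrum` with elements `counts_per_day`
#'   (named numeric, one entry per threshold), `mean_bout_length_min`,
#'   `total_mvpa_min`, `n_bouts`, `n_valid_days` and `no_bouts` (flag; when
#'   `TRUE`, `mean_bout_length_min` is reported as 0).
#' @export
bout_spectrum <- function(bouts, n_valid_days,
                          duration_thresholds = c(2, 5, 10, 20)) {
  if (!is.numeric(n_valid_days) || length(n_valid_days) != 1L ||
      is.na(n_valid_days) || n_valid_days < 1) {
    abort("bout spectrum is undefined with zero valid days")
  }
  duration_thresholds <- sort(unique(as.integer(duration_thresholds)))
  if (any(duration_thresholds < 1)) abort("duration thresholds must be >= 1 minute")
  durations <- if (nrow(bouts)) bouts$duration_min else integer()
  counts <- vapply(duration_thresholds,
                   function(d) sum(durations >= d) / n_valid_days,
                   numeric(1))
  names(counts) <- as.character(duration_thresholds)
  structure(
    list(
      counts_per_day = counts,
      mean_bout_length_min = if (length(durations)) mean(durations) else 0,
      total_mvpa_min = sum(durations) / n_valid_days,
      n_bouts = length(durations),
      n_valid_days = n_valid_days,
      no_bouts = length(durations) == 0L
    ),
    class = "bout_spectrum"
  )
}

#' @export
print.bout_spectrum <- function(x, ...) {
  cat("MVPA bout spectrum over", x$n_valid_days, "valid day(s)\n")
  cat("  bouts/day at >= {", paste(names(x$counts_per_day), collapse = ", "),
      "} min:", paste(round(x$counts_per_day, 2), collapse = ", "), "\n")
  cat("  mean bout length:", round(x$mean_bout_length_min, 2), "min",
      if (x$no_bouts) "(no bouts)" else "", "\n")
  cat("  total MVPA:", round(x$total_mvpa_min, 1), "min/day\n")
  invisible(x)
}
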