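#' Read a minute-epoch accelerometer CSV
#'
#' The canonical schema is a comma-separated file with a header row and
#' columns `participant_id,timepoint,timestamp,mets,steps[,worn]`:
#' ISO-8601 timestamps at minute resolution, MET values as non-negative
#' reals, steps as non-negative integers and an optional logical `worn`
#' flag. When `worn` is absent an epoch is treated as non-worn iff its
#' `mets` value is missing — the only defensible proxy when the device
#' reports no off-body channel.
#'
#' Malformed rows (unparseable timestamp, negative METs or steps, unknown
#' timepoint label, worn epochs with missing METs) are dropped, counted and
#' reported via a warning and the `n_malformed` attribute. A duplicated
#' minute within a participant-day is a hard data error naming that day.
#'
#' @param path path to the CSV file.
#' @param schema optional named character vector mapping canonical column
#'   names (`participant_id`, `timepoint`, ...) to the column names used in
#'   the file, e.g. `c(mets = "METS", steps = "step_count")`.
#'
#' @return A tibble of epochs ordered by participant, timepoint and
#'   timestamp, with columns `participant_id` (character), `timepoint`
#'   (factor baseline/discharge), `timestamp` (POSIXct UTC), `date`,
#'   `mets`, `steps`, `worn`; attribute `n_malformed` counts dropped rows.
#' @export
read_epoch_csv <- function(path, schema = NULL) {
  if (!file.exists(path)) abort(paste0("epoch file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  canonical <- c("participant_id", "timepoint", "timestamp", "mets", "steps", "worn")
  map <- setNames(canonical, canonical)
  if (!is.null(schema)) map[names(schema)] <- unname(schema)
  required <- canonical[canonical != "worn"]
  missing_cols <- required[!map[required] %in% names(raw)]
  if (length(missing_cols)) {
    abort(paste0("epoch file is missing required column(s): ",
                 paste(map[missing_cols], collapse = ", ")))
  }
  x <- tibble(
    participant_id = raw[[map["participant_id"]]],
    timepoint = raw[[map["timepoint"]]],
    timestamp = readr::parse_datetime(raw[[map["timestamp"]]]),
    mets = suppressWarnings(as.numeric(raw[[map["mets"]]])),
    steps = suppressWarnings(as.numeric(raw[[map["steps"]]]))
  )
  has_worn <- map[["worn"]] %in% names(raw)
  x$worn <- if (has_worn) {
    toupper(trimws(raw[[map["worn"]]])) %in% c("TRUE", "T", "1", "YES")
  } else {
    !is.na(x$mets)
  }

  bad <- is.na(x$timestamp) |
    !x$timepoint %in% c("baseline", "discharge") |
    (!is.na(x$mets) & x$mets < 0) |
    (is.na(x$steps) | x$steps < 0) |
    (x$worn & is.na(x$mets))
  n_bad <- sum(bad)
  if (n_bad > 0) {
    warn(paste0("dropped ", n_bad, " malformed epoch row(s)"))
    x <- x[!bad, , drop = FALSE]
  }
  attr(x, "n_malformed") <- n_bad

  x$timepoint <- factor(x$timepoint, levels = c("baseline", "discharge"))
  attr(x$timestamp, "tzone") <- "UTC"
  x$date <- as.Date(x$timestamp, tz = "UTC")
  x$steps <- as.integer(x$steps)
  x <- arrange(x, .data$participant_id, .data$timepoint, .data$timestamp)

  dup <- x |>
    group_by(.data$participant_id, .data$timepoint, .data$date) |>
    summarise(dup = anyDuplicated(.data$timestamp) > 0, .groups = "drop") |>
    filter(.data$dup)
  if (nrow(dup)) {
    abort(paste0("duplicated minute within participant-day: ",
                 paste0(dup$participant_id, "/", dup$timepoint, "/", dup$date,
                        collapse = "; ")))
  }
  x[, c("participant_id", "timepoint", "timestamp", "date", "mets", "steps", "worn")]
}

#' Write epochs in the canonical CSV schema
#'
#' Columns are written in the fixed canonical order with ISO-8601 UTC
#' timestamps, so that `write_epoch_csv()` followed by [read_epoch_csv()]
#' round-trips records exactly, and identical inputs produce byte-identical
#' files.
#'
#' @param epochs epoch tibble (as from [read_epoch_csv()] or
#'   [simulate_cohort()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(epochs, path) {
  out <- tibble(
    participant_id = epochs$participant_id,
    timepoint = as.character(epochs$timepoint),
    timestamp = format(epochs$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    mets = epochs$mets,
    steps = epochs$steps,
    worn = epochs$worn
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read the participant manifest CSV
#'
#' Schema: `participant_id,arm,age,bmi,fev1_pct_pred,sex[,iswt_m,eswt_s]`,
#' one row per participant; `arm` is `web` or `conventional`. A duplicated
#' `participant_id` is a data error; an empty file yields an empty tibble
#' with a warning.
#'
#' @param path path to the manifest CSV.
#' @return Tibble of participants with `arm` as a factor
#'   (web/conventional).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("manifest file not found: ", path))
  x <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    arm = readr::col_character(),
    age = readr::col_double(),
    bmi = readr::col_double(),
    fev1_pct_pred = readr::col_double(),
    sex = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  required <- c("participant_id", "arm", "age", "bmi", "fev1_pct_pred", "sex")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    abort(paste0("manifest is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0L) {
    warn("manifest file is empty")
    return(x)
  }
  if (anyDuplicated(x$participant_id)) {
    abort(paste0("duplicated participant_id in manifest: ",
                 paste(unique(x$participant_id[duplicated(x$participant_id)]),
                       collapse = ", ")))
  }
  bad_arm <- setdiff(unique(x$arm), c("web", "conventional"))
  if (length(bad_arm)) {
    abort(paste0("unknown arm label(s): ", paste(bad_arm, collapse = ", ")))
  }
  x$arm <- factor(x$arm, levels = c("web", "conventional"))
  x
}

#' Write a participant manifest CSV
#'
#' @param manifest manifest tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  out <- manifest
  out$arm <- as.character(out$arm)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Reconcile epoch participants against the manifest
#'
#' Every participant seen in the epoch data should have a manifest row;
#' ids failing that (and manifest ids with no epoch data) are listed so a
#' run log can report them.
#'
#' @param epochs epoch tibble.
#' @param manifest manifest tibble.
#' @return List with character vectors `epochs_not_in_manifest` and
#'   `manifest_not_in_epochs`.
#' @export
reconcile_manifest <- function(epochs, manifest) {
  eid <- unique(epochs$participant_id)
  mid <- unique(manifest$participant_id)
  list(
    epochs_not_in_manifest = sort(setdiff(eid, mid)),
    manifest_not_in_epochs = sort(setdiff(mid, eid))
  )
}
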