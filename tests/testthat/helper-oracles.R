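# Independent oracles and fixture builders shared across the suite.

# Build a one-day epoch tibble on a contiguous 1-minute grid.
make_day <- function(mets, worn = TRUE, steps = 0,
                     start = "2019-01-07 09:00:00",
                     participant_id = "P01", timepoint = "baseline") {
  n <- length(mets)
  tibble::tibble(
    participant_id = participant_id,
    timepoint = timepoint,
    timestamp = as.POSIXct(start, tz = "UTC") + 60 * (seq_len(n) - 1),
    mets = mets,
    steps = rep_len(steps, n),
    worn = rep_len(worn, n)
  )
}

# Quadratic brute-force bout finder: checks every interval of contiguous
# minutes for being an all-MVPA worn run and for maximality. Independent of
# the rle-based implementation.
brute_force_bout_durations <- function(mets, worn = rep(TRUE, length(mets)),
                                       moderate_min = 3) {
  n <- length(mets)
  eligible <- !is.na(mets) & worn & mets >= moderate_min
  durations <- integer()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!all(eligible[i:j])) next
      left_ok <- i == 1 || !eligible[i - 1]
      right_ok <- j == n || !eligible[j + 1]
      if (left_ok && right_ok) durations <- c(durations, j - i + 1L)
    }
  }
  sort(durations)
}

# Brute-force wear filter over a toy cohort of per-day wear minutes.
brute_force_inclusion <- function(wear_minutes_by_participant,
                                  min_wear = 480, min_days = 4) {
  names(which(vapply(wear_minutes_by_participant,
                     function(w) sum(w >= min_wear) >= min_days,
                     logical(1))))
}

# Long-format mixed-design dataset: one between factor (2 arms, sizes n1/n2),
# one within factor (2 timepoints). Null unless deltas given.
make_mixed_data <- function(n1 = 20, n2 = 34, delta_time = 0,
                            delta_interaction = 0, sd_subject = 1, sd_noise = 1) {
  n <- n1 + n2
  id <- sprintf("S%03d", seq_len(n))
  arm <- rep(c("web", "conventional"), c(n1, n2))
  b <- rnorm(n, 0, sd_subject)
  base <- b + rnorm(n, 0, sd_noise)
  dis <- b + delta_time + delta_interaction * (arm == "web") + rnorm(n, 0, sd_noise)
  tibble::tibble(
    participant_id = rep(id, 2),
    arm = rep(arm, 2),
    timepoint = rep(c("baseline", "discharge"), each = n),
    y = c(base, dis)
  )
}

# Reference mixed-ANOVA SS via stats::aov with an Error stratum — an
# independent route through R's projection machinery.
aov_mixed_ss <- function(data) {
  d <- data.frame(y = data$y, g = factor(data$arm), t = factor(data$timepoint),
                  s = factor(data$participant_id))
  fit <- stats::aov(y ~ g * t + Error(s), data = d)
  sm <- summary(fit)
  between <- sm[["Error: s"]][[1]]
  within <- sm[["Error: Within"]][[1]]
  list(
    group = between["g", "Sum Sq"],
    subj = between["Residuals", "Sum Sq"],
    time = within["t", "Sum Sq"],
    inter = within["g:t", "Sum Sq"],
    err = within["Residuals", "Sum Sq"]
  )
}
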