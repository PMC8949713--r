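#' Daily activity profile for the epoch simulator
#'
#' Parameterises one arm-timepoint's minute-epoch generating process:
#' a sedentary MET background inside a daily wear window, a Poisson number
#' of MVPA bouts per day with geometric bout lengths (memoryless, with
#' analytically tractable tail probabilities: a bout lasts at least d
#' minutes with probability `(1 - p)^(d - 1)`), a planted budget of light
#' activity minutes, and class-specific step rates. A day is sampled
#' invalid (worn < 480 min) with probability `p_invalid_day`.
#'
#' @param basal_met_mean,basal_met_sd Gaussian MET level of sedentary worn
#'   minutes (clipped to stay at or below the light cut-point).
#' @param light_rate expected light-activity minutes per day (Poisson).
#' @param light_met_mean,light_met_sd Gaussian MET level of light minutes
#'   (clipped into the open light band).
#' @param mvpa_bout_rate expected MVPA bouts per day (Poisson).
#' @param bout_length_p geometric parameter p in (0, 1]; mean bout length
#'   is `1/p` minutes.
#' @param bout_met_mean,bout_met_sd Gaussian MET level of bout minutes;
#'   `bout_met_mean` must lie in the moderate band \[3, 6\] and draws are
#'   clipped into it, so every planted bout minute is MVPA.
#' @param steps_per_mvpa_min,steps_per_light_min Poisson step rates per
#'   minute in each class (sedentary minutes take no steps).
#' @param wear_start_min,wear_end_min daily wear window in minutes from
#'   midnight (defaults 480 and 1320: 08:00-22:00, 840 worn minutes).
#' @param p_invalid_day probability that a day's wear is truncated below
#'   the 480-minute validity criterion.
#'
#' @return An object of class `activity_profile`.
#' @export
activity_profile <- function(basal_met_mean = 1.1, basal_met_sd = 0.15,
                             light_rate = 120, light_met_mean = 2.2,
                             light_met_sd = 0.35,
                             mvpa_bout_rate = 32.8, bout_length_p = 0.357,
                             bout_met_mean = 3.3, bout_met_sd = 0.25,
                             steps_per_mvpa_min = 45, steps_per_light_min = 11.1,
                             wear_start_min = 480L, wear_end_min = 1320L,
                             p_invalid_day = 0.1) {
  p <- list(basal_met_mean = basal_met_mean, basal_met_sd = basal_met_sd,
            light_rate = light_rate, light_met_mean = light_met_mean,
            light_met_sd = light_met_sd, mvpa_bout_rate = mvpa_bout_rate,
            bout_length_p = bout_length_p, bout_met_mean = bout_met_mean,
            bout_met_sd = bout_met_sd, steps_per_mvpa_min = steps_per_mvpa_min,
            steps_per_light_min = steps_per_light_min,
            wear_start_min = as.integer(wear_start_min),
            wear_end_min = as.integer(wear_end_min),
            p_invalid_day = p_invalid_day)
  if (any(vapply(p[c("light_rate", "mvpa_bout_rate", "steps_per_mvpa_min",
                     "steps_per_light_min")], `<`, logical(1), 0))) {
    abort("activity rates must be non-negative")
  }
  if (p$bout_length_p <= 0 || p$bout_length_p > 1) abort("bout_length_p must be in (0, 1]")
  if (p$bout_met_mean < 3 || p$bout_met_mean > 6) {
    abort("bout_met_mean must lie in the moderate band [3, 6]")
  }
  if (p$wear_start_min < 0 || p$wear_end_min > 1440 ||
      p$wear_end_min <= p$wear_start_min) {
    abort("wear window must lie within the day and have positive length")
  }
  if (p$p_invalid_day < 0 || p$p_invalid_day > 1) abort("p_invalid_day must be a probability")
  structure(p, class = "activity_profile")
}

#' Intervention effect on an activity profile
#'
#' Encodes the two response phenotypes seen after rehabilitation: a
#' short-bout shift (more bouts per day, `delta_bout_rate`), a long-bout
#' shift (smaller geometric p lengthens bouts, `delta_bout_length_p` as a
#' multiplier on p), and an overall step-rate multiplier
#' (`delta_steps_scale`).
#'
#' @param delta_bout_rate additive change in expected bouts/day.
#' @param delta_bout_length_p multiplier on the geometric parameter p
#'   (values below 1 lengthen bouts).
#' @param delta_steps_scale multiplier on both step rates.
#' @return An object of class `intervention_effect`.
#' @export
intervention_effect <- function(delta_bout_rate = 0, delta_bout_length_p = 1,
                                delta_steps_scale = 1) {
  structure(list(delta_bout_rate = delta_bout_rate,
                 delta_bout_length_p = delta_bout_length_p,
                 delta_steps_scale = delta_steps_scale),
            class = "intervention_effect")
}

#' Apply an intervention effect to a profile
#'
#' @param profile an [activity_profile()].
#' @param effect an [intervention_effect()].
#' @return The modified [activity_profile()] (revalidated).
#' @export
apply_effect <- function(profile, effect) {
  stopifnot(inherits(profile, "activity_profile"),
            inherits(effect, "intervention_effect"))
  args <- unclass(profile)
  args$mvpa_bout_rate <- args$mvpa_bout_rate + effect$delta_bout_rate
  args$bout_length_p <- args$bout_length_p * effect$delta_bout_length_p
  args$steps_per_mvpa_min <- args$steps_per_mvpa_min * effect$delta_steps_scale
  args$steps_per_light_min <- args$steps_per_light_min * effect$delta_steps_scale
  do.call(activity_profile, args)
}

#' Trial-calibrated default arm profiles
#'
#' Baseline profiles for the two arms, calibrated to the published
#' activity-pattern anchors of the trial the package emulates: web arm
#' 32.8 bouts/day with geometric p = 0.357 (mean bout length 2.8 min,
#' 21.1 bouts/day at the 2-minute threshold, ~5465 steps/day), conventional
#' arm 28.6 bouts/day with p = 0.3704 (mean length 2.7 min, 18 bouts/day at
#' 2 minutes, ~5300 steps/day).
#'
#' @return Named list of two [activity_profile()] objects (`web`,
#'   `conventional`).
#' @export
default_profiles <- function() {
  list(
    web = activity_profile(mvpa_bout_rate = 32.8, bout_length_p = 0.357,
                           steps_per_mvpa_min = 45, steps_per_light_min = 11.1),
    conventional = activity_profile(mvpa_bout_rate = 28.6, bout_length_p = 0.3704,
                                    steps_per_mvpa_min = 45, steps_per_light_min = 15.2)
  )
}

#' Trial-calibrated default intervention effects
#'
#' The web arm's response is a short-bout shift with a small step-rate
#' rise (about +12% steps/day); the conventional arm's is a long-bout
#' shift (p multiplied by 0.964, lengthening mean bouts from 2.7 to 2.8
#' minutes and raising the expected count of 20-minute bouts by about
#' 49%, with steps up about 2%).
#'
#' @return Named list of two [intervention_effect()] objects.
#' @export
default_effects <- function() {
  list(
    web = intervention_effect(delta_bout_rate = 4, delta_bout_length_p = 1,
                              delta_steps_scale = 1.03),
    conventional = intervention_effect(delta_bout_rate = 0,
                                       delta_bout_length_p = 0.964,
                                       delta_steps_scale = 1)
  )
}

# sample a uniform-ish composition of `total` into `k` non-negative parts
sample_gaps <- function(total, k) {
  if (k == 1L) return(total)
  as.vector(rmultinom(1, total, rep(1 / k, k)))
}

#' Simulate one participant-day of minute epochs
#'
#' Generates 1440 one-minute epochs for a calendar day under a profile:
#' epochs are worn inside the wear window (truncated when the day is
#' sampled invalid); a Poisson number of MVPA bouts with geometric lengths
#' is placed uniformly in the worn window with at least one non-MVPA
#' minute between bouts (so every planted bout is a maximal run); remaining
#' worn minutes are light or sedentary; steps accumulate as Poisson counts
#' at class rates. Non-worn epochs carry `mets = NA`, `steps = 0`.
#'
#' If the drawn bouts cannot fit in the worn window they are redrawn a
#' bounded number of times before erroring.
#'
#' @param profile an [activity_profile()].
#' @param participant_id,timepoint,date identifiers stamped on the epochs.
#' @param seed optional integer seed; when `NULL` the current RNG stream
#'   is used.
#'
#' @return List with `epochs` (1440-row tibble) and `truth`, the planted
#'   ledger: `day` (one-row bookkeeping tibble: worn minutes, planted
#'   validity, bout count, MVPA/light/sedentary minutes, steps) and
#'   `bouts` (planted bout starts and lengths).
#' @export
simulate_participant_day <- function(profile, participant_id = "P01",
                                     timepoint = "baseline",
                                     date = as.Date("2019-01-07"),
                                     seed = NULL) {
  stopifnot(inherits(profile, "activity_profile"))
  if (!is.null(seed)) set.seed(seed)
  w0 <- profile$wear_start_min
  w1 <- profile$wear_end_min
  invalid <- runif(1) < profile$p_invalid_day
  if (invalid) {
    # truncate wear below the 480-minute validity criterion
    w1 <- w0 + sample(60:479, 1)
    w1 <- min(w1, 1440L)
  }
  W <- w1 - w0
  worn_idx <- (w0 + 1L):w1

  # expected bouts scale with available wear, so truncated (invalid) days
  # keep the same bout intensity per worn hour
  lambda <- profile$mvpa_bout_rate * W / (profile$wear_end_min - profile$wear_start_min)
  # draw and place bouts; redraw when they cannot fit with 1-min separators
  for (attempt in 1:50) {
    n_bouts <- rpois(1, lambda)
    lens <- if (n_bouts > 0) rgeom(n_bouts, profile$bout_length_p) + 1L else integer()
    free <- W - sum(lens) - max(n_bouts - 1L, 0L)
    if (free >= 0) break
    if (attempt == 50) abort("could not place bouts in the wear window")
  }
  mets <- rep(NA_real_, 1440)
  cls <- rep(NA_character_, 1440)
  bout_start <- integer(n_bouts)
  if (n_bouts > 0) {
    gaps <- sample_gaps(free, n_bouts + 1L)
    pos <- w0
    for (b in seq_len(n_bouts)) {
      pos <- pos + gaps[b] + (if (b > 1) 1L else 0L)
      bout_start[b] <- pos + 1L
      span <- (pos + 1L):(pos + lens[b])
      mets[span] <- pmin(pmax(rnorm(lens[b], profile$bout_met_mean,
                                    profile$bout_met_sd), 3), 6)
      cls[span] <- "mvpa"
      pos <- pos + lens[b]
    }
  }
  rest <- setdiff(worn_idx, which(cls == "mvpa"))
  n_light <- min(rpois(1, profile$light_rate), length(rest))
  light_idx <- if (n_light > 0) sample(rest, n_light) else integer()
  sed_idx <- setdiff(rest, light_idx)
  mets[light_idx] <- pmin(pmax(rnorm(n_light, profile$light_met_mean,
                                     profile$light_met_sd), 1.6), 2.9)
  mets[sed_idx] <- pmin(pmax(rnorm(length(sed_idx), profile$basal_met_mean,
                                   profile$basal_met_sd), 0.9), 1.5)
  cls[light_idx] <- "light"
  cls[sed_idx] <- "sedentary"

  steps <- integer(1440)
  mvpa_idx <- which(cls == "mvpa")
  steps[mvpa_idx] <- rpois(length(mvpa_idx), profile$steps_per_mvpa_min)
  steps[light_idx] <- rpois(n_light, profile$steps_per_light_min)

  worn <- logical(1440)
  worn[worn_idx] <- TRUE
  ts0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  epochs <- tibble(
    participant_id = participant_id,
    timepoint = timepoint,
    timestamp = ts0 + 60 * (0:1439),
    mets = mets, steps = steps, worn = worn
  )
  truth_day <- tibble(
    participant_id = participant_id, timepoint = timepoint, date = date,
    worn_minutes = W, planted_valid = W >= 480L,
    n_bouts = n_bouts, mvpa_minutes = sum(lens),
    light_minutes = n_light, sedentary_minutes = length(sed_idx),
    steps = sum(steps)
  )
  truth_bouts <- tibble(
    participant_id = participant_id, timepoint = timepoint, date = date,
    start_min = bout_start, length_min = as.integer(lens)
  )
  list(epochs = epochs, truth = list(day = truth_day, bouts = truth_bouts))
}

#' Simulate a two-arm, two-timepoint minute-epoch cohort
#'
#' Builds a full trial-like dataset: a manifest with arm assignment and
#' clinical covariates drawn from arm-specific normals calibrated to the
#' published baseline characteristics (age, BMI, FEV1 percent predicted,
#' walking-test covariates, sex mix), and per participant `n_days` of
#' minute epochs at baseline plus `n_days` at discharge generated from the
#' arm's baseline profile and its effect-modified discharge profile. One
#' master seed fans out to per-participant streams, so identical seeds
#' give byte-identical CSVs.
#'
#' @param n_web,n_conventional arm sizes (defaults 20 and 34, the trial's
#'   complete-data arms).
#' @param profiles named list of baseline [activity_profile()]s per arm
#'   (default [default_profiles()]).
#' @param effects named list of [intervention_effect()]s per arm (default
#'   [default_effects()]).
#' @param n_days monitored days per timepoint (default 7).
#' @param seed master integer seed.
#' @param out_dir optional directory; when given, `epochs.csv` and
#'   `manifest.csv` are written there.
#'
#' @return List with `epochs`, `manifest`, `truth` (list of `days` and
#'   `bouts` ledgers) and, when written, `paths`.
#' @export
simulate_cohort <- function(n_web = 20, n_conventional = 34,
                            profiles = default_profiles(),
                            effects = default_effects(),
                            n_days = 7, seed = 20130315, out_dir = NULL) {
  stopifnot(n_web >= 1, n_conventional >= 1)
  set.seed(seed %% .Machine$integer.max)
  n_total <- n_web + n_conventional
  ids <- c(sprintf("W%02d", seq_len(n_web)),
           sprintf("C%02d", seq_len(n_conventional)))
  arms <- c(rep("web", n_web), rep("conventional", n_conventional))

  # covariates calibrated to the published baseline characteristics
  cov_par <- list(
    web = list(age = c(68.3, 6.5), bmi = c(27.2, 5.5), fev1 = c(54.2, 26.9),
               p_male = 18 / 20, iswt = c(338.5, 185.7), eswt = c(263.9, 250.1)),
    conventional = list(age = c(67.4, 8.6), bmi = c(29.8, 6.6), fev1 = c(55.8, 19.4),
                        p_male = 19 / 34, iswt = c(286.8, 159.4), eswt = c(256.2, 157.1))
  )
  draw <- function(par, n) pmax(rnorm(n, par[1], par[2]), 0.2 * par[1])
  manifest <- bind_rows(lapply(c("web", "conventional"), function(a) {
    n <- if (a == "web") n_web else n_conventional
    cp <- cov_par[[a]]
    tibble(
      participant_id = ids[arms == a],
      arm = a,
      age = round(draw(cp$age, n), 1),
      bmi = round(draw(cp$bmi, n), 1),
      fev1_pct_pred = round(pmax(rnorm(n, cp$fev1[1], cp$fev1[2]), 15), 1),
      sex = ifelse(runif(n) < cp$p_male, "male", "female"),
      iswt_m = round(draw(cp$iswt, n), 1),
      eswt_s = round(draw(cp$eswt, n), 1)
    )
  }))
  manifest$arm <- factor(manifest$arm, levels = c("web", "conventional"))

  part_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  base_dates <- as.Date("2019-01-07") + seq_len(n_days) - 1
  dis_dates <- as.Date("2019-03-11") + seq_len(n_days) - 1

  epochs <- vector("list", n_total * n_days * 2L)
  t_days <- vector("list", n_total * n_days * 2L)
  t_bouts <- vector("list", n_total * n_days * 2L)
  k <- 0L
  for (i in seq_len(n_total)) {
    set.seed(part_seeds[i])
    arm <- arms[i]
    prof_base <- profiles[[arm]]
    prof_dis <- apply_effect(prof_base, effects[[arm]])
    for (tp in c("baseline", "discharge")) {
      prof <- if (tp == "baseline") prof_base else prof_dis
      dates <- if (tp == "baseline") base_dates else dis_dates
      for (d in seq_len(n_days)) {
        sim <- simulate_participant_day(prof, ids[i], tp, dates[d])
        k <- k + 1L
        epochs[[k]] <- sim$epochs
        t_days[[k]] <- sim$truth$day
        t_bouts[[k]] <- sim$truth$bouts
      }
    }
  }
  epochs <- bind_rows(epochs)
  epochs$timepoint <- factor(epochs$timepoint, levels = c("baseline", "discharge"))
  epochs$date <- as.Date(epochs$timestamp, tz = "UTC")
  epochs <- epochs[, c("participant_id", "timepoint", "timestamp", "date",
                       "mets", "steps", "worn")]
  truth <- list(days = bind_rows(t_days), bouts = bind_rows(t_bouts))

  out <- list(epochs = epochs, manifest = manifest, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out$paths <- list(
      epochs = write_epoch_csv(epochs, file.path(out_dir, "epochs.csv")),
      manifest = write_manifest(manifest, file.path(out_dir, "manifest.csv"))
    )
  }
  out
}
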