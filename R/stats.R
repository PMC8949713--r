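#' Two-tailed independent-samples t test
#'
#' Classical Student t with pooled variance by default (the generic
#' "independent samples t test"); Welch's unequal-variance form is
#' available via `var_equal = FALSE`. Degenerate inputs with zero variance
#' in both groups are flagged: equal means give the conventional
#' `t = 0, p = 1`, unequal means `p = 0`.
#'
#' @param x,y numeric vectors, each of length at least 2.
#' @param var_equal pool the variances (default `TRUE`).
#' @param alpha nominal two-sided significance level carried in the result.
#'
#' @return One-row tibble: `test`, `estimate` (mean of `x` minus mean of
#'   `y`), `statistic`, `df`, `p_value`, `alpha`, `note` (degenerate-case
#'   flag, else `NA`).
#' @export
independent_t <- function(x, y, var_equal = TRUE, alpha = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) abort("missing values in t-test input")
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) abort("each group needs at least 2 observations")
  est <- mean(x) - mean(y)
  v1 <- var(x); v2 <- var(y)
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- if (se > 0) se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)) else n1 + n2 - 2
  }
  if (se == 0) {
    return(stat_row("independent_t", est,
                    statistic = 0, df = df,
                    p_value = if (est == 0) 1 else 0, alpha = alpha,
                    note = "zero variance in both groups"))
  }
  t <- est / se
  stat_row("independent_t", est, t, df, 2 * pt(-abs(t), df), alpha)
}

#' Two-tailed paired-samples t test
#'
#' One-sample t on the within-pair differences `after - before`, pairs
#' aligned by position (i.e. by participant). Zero-variance differences
#' are flagged: all-zero differences give `t = 0, p = 1`; equal nonzero
#' differences give the limiting `p = 0`.
#'
#' @param before,after numeric vectors of equal length (n >= 2), aligned
#'   by participant.
#' @inheritParams independent_t
#' @return One-row tibble as in [independent_t()]; `estimate` is the mean
#'   difference `after - before`.
#' @export
paired_t <- function(before, after, alpha = 0.05) {
  if (length(before) != length(after)) abort("paired samples differ in length")
  d <- as.numeric(after) - as.numeric(before)
  if (anyNA(d)) abort("missing values in t-test input")
  n <- length(d)
  if (n < 2) abort("paired t test needs at least 2 pairs")
  est <- mean(d)
  se <- sd(d) / sqrt(n)
  if (se == 0) {
    return(stat_row("paired_t", est, statistic = 0, df = n - 1,
                    p_value = if (est == 0) 1 else 0, alpha = alpha,
                    note = "zero variance in differences"))
  }
  t <- est / se
  stat_row("paired_t", est, t, n - 1, 2 * pt(-abs(t), n - 1), alpha)
}

#' Two-way mixed-design repeated-measures ANOVA
#'
#' One between-subjects factor (trial arm) crossed with one within-subjects
#' factor (timepoint), every subject measured at every timepoint. The sum
#' of squares is partitioned into between-subjects terms (group;
#' subjects-within-group) and within-subjects terms (time; group-by-time
#' interaction; time-by-subjects-within-group error). Because every subject
#' contributes all time levels, cell frequencies are proportional even with
#' unequal arm sizes, the weighted decomposition is orthogonal and exact,
#' and the interaction sum of squares coincides with its Type III value.
#' With only two time levels sphericity holds trivially. Subjects missing a
#' timepoint are dropped (complete-case) with a warning, or raise an error
#' under `strict = TRUE`.
#'
#' @param data data frame in long format.
#' @param outcome name of the numeric outcome column.
#' @param subject,group,time names of the subject id, between-factor and
#'   within-factor columns.
#' @param strict error (instead of warn-and-drop) on subjects with
#'   incomplete timepoints.
#' @param alpha nominal significance level carried in the result.
#'
#' @return Tibble with one row per effect (`group`, `time`, `group:time`),
#'   columns `test`, `effect`, `ss`, `df`, `ms`, `error_ss`, `error_df`,
#'   `statistic` (F), `p_value`, `alpha`, `note`.
#' @export
mixed_anova <- function(data, outcome, subject = "participant_id",
                        group = "arm", time = "timepoint",
                        strict = FALSE, alpha = 0.05) {
  d <- data.frame(
    y = as.numeric(data[[outcome]]),
    s = as.character(data[[subject]]),
    g = as.character(data[[group]]),
    t = as.character(data[[time]])
  )
  d <- d[complete.cases(d), , drop = FALSE]
  tlev <- sort(unique(d$t))
  nt <- length(tlev)
  if (nt < 2) abort("mixed_anova needs at least 2 time levels")
  cnt <- table(d$s)
  incomplete <- names(cnt)[cnt != nt]
  # a subject seen fewer (or more) times than there are levels is incomplete
  by_subj <- tapply(d$t, d$s, function(x) length(unique(x)))
  incomplete <- union(incomplete, names(by_subj)[by_subj != nt])
  if (length(incomplete)) {
    msg <- paste0(length(incomplete), " subject(s) lack a complete set of timepoints")
    if (strict) abort(msg)
    warn(paste0(msg, "; dropped (complete-case analysis)"))
    d <- d[!d$s %in% incomplete, , drop = FALSE]
  }
  glev <- sort(unique(d$g))
  if (length(glev) < 2) abort("mixed_anova needs at least 2 groups")
  subj_grp <- tapply(d$g, d$s, function(x) x[1])
  if (any(table(subj_grp[unique(d$s)]) < 2)) abort("each group needs at least 2 subjects")

  gm <- mean(d$y)
  n_subj <- length(unique(d$s))
  a <- length(glev)

  subj_means <- tapply(d$y, d$s, mean)
  grp_of_subj <- tapply(d$g, d$s, function(x) x[1])
  n_g <- table(grp_of_subj)[glev]
  grp_means <- tapply(d$y, d$g, mean)[glev]
  time_means <- tapply(d$y, d$t, mean)[tlev]
  cell_means <- tapply(d$y, list(d$g, d$t), mean)[glev, tlev, drop = FALSE]

  ss_total <- sum((d$y - gm)^2)
  ss_between_subj <- nt * sum((subj_means - gm)^2)
  ss_group <- nt * sum(as.numeric(n_g) * (grp_means - gm)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_within <- ss_total - ss_between_subj
  ss_time <- n_subj * sum((time_means - gm)^2)
  ss_inter <- sum(as.numeric(n_g) %o% rep(1, nt) *
                    (cell_means - outer(grp_means, rep(1, nt)) -
                       outer(rep(1, a), time_means) + gm)^2)
  ss_err_within <- ss_within - ss_time - ss_inter

  df_group <- a - 1
  df_subj <- n_subj - a
  df_time <- nt - 1
  df_inter <- (a - 1) * (nt - 1)
  df_err <- df_subj * df_time

  f_of <- function(ss, df, ess, edf) (ss / df) / (ess / edf)
  eff <- function(name, ss, df, ess, edf) {
    f <- f_of(ss, df, ess, edf)
    tibble(test = "mixed_anova", effect = name, ss = ss, df = df,
           ms = ss / df, error_ss = ess, error_df = edf,
           statistic = f, p_value = pf(f, df, edf, lower.tail = FALSE),
           alpha = alpha, note = NA_character_)
  }
  bind_rows(
    eff("group", ss_group, df_group, ss_subj_within, df_subj),
    eff("time", ss_time, df_time, ss_err_within, df_err),
    eff("group:time", ss_inter, df_inter, ss_err_within, df_err)
  )
}

#' Spearman rank correlation with mid-rank ties
#'
#' The rank correlation coefficient computed as the Pearson correlation of
#' mid-ranks (tie-aware), with the two-sided p-value from the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom. Constant input has no defined rank correlation and
#' is an error.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @inheritParams independent_t
#' @return One-row tibble as in [independent_t()]; `estimate` is rho.
#' @export
spearman_cor <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) abort("spearman inputs differ in length")
  keep <- !(is.na(x) | is.na(y))
  x <- as.numeric(x)[keep]; y <- as.numeric(y)[keep]
  n <- length(x)
  if (n < 3) abort("spearman correlation needs at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  sx <- sqrt(sum((rx - mean(rx))^2))
  sy <- sqrt(sum((ry - mean(ry))^2))
  if (sx == 0 || sy == 0) abort("undefined correlation: constant input")
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) / (sx * sy)
  if (abs(rho) >= 1 - 1e-15) {
    return(stat_row("spearman", sign(rho), statistic = sign(rho) * Inf,
                    df = n - 2, p_value = 0, alpha = alpha,
                    note = "perfect monotone association"))
  }
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  stat_row("spearman", rho, t, n - 2, 2 * pt(-abs(t), n - 2), alpha)
}

#' Spearman screen of clinical covariates against an activity outcome
#'
#' One rank correlation per clinical field at each requested timepoint,
#' with the trial arms pooled. Per-field errors (e.g. a constant input) are
#' captured in the `note` column instead of aborting the screen. No
#' multiple-testing adjustment is applied; report the number of tests
#' alongside alpha.
#'
#' @param cohort cohort table (participant summaries joined with the
#'   manifest) containing the clinical fields, `timepoint` and the
#'   activity field.
#' @param pa_field name of the activity outcome column (e.g. `"bouts_10"`).
#' @param clinical_fields character vector of covariate columns.
#' @param timepoints timepoints to screen (default both present).
#' @inheritParams independent_t
#' @return Tibble with one row per timepoint-by-field combination.
#' @export
correlation_screen <- function(cohort, pa_field,
                               clinical_fields = c("age", "bmi", "fev1_pct_pred"),
                               timepoints = NULL, alpha = 0.05) {
  tps <- timepoints %||% sort(unique(as.character(cohort$timepoint)))
  rows <- list()
  for (tp in tps) {
    sub <- cohort[as.character(cohort$timepoint) == tp, , drop = FALSE]
    for (f in clinical_fields) {
      res <- tryCatch(
        spearman_cor(sub[[f]], sub[[pa_field]], alpha = alpha),
        error = function(e) stat_row("spearman", NA_real_, NA_real_, NA_real_,
                                     NA_real_, alpha, note = conditionMessage(e))
      )
      res$timepoint <- tp
      res$clinical_field <- f
      res$pa_field <- pa_field
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- bind_rows(rows)
  out[, c("timepoint", "clinical_field", "pa_field", "test", "estimate",
          "statistic", "df", "p_value", "alpha", "note")]
}

#' Format a p-value for display
#'
#' Three decimals with the `<.001` convention; the underlying value is
#' never rounded in stored outputs.
#'
#' @param p numeric p-value(s).
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "<.001", sub("^0", "", sprintf("%.3f", p))))
}

stat_row <- function(test, estimate, statistic, df, p_value, alpha = 0.05,
                     note = NA_character_) {
  tibble(test = test, estimate = estimate, statistic = statistic, df = df,
         p_value = p_value, alpha = alpha, note = note)
}
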