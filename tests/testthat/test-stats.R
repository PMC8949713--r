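test_that("independent t matches the reference implementation", {
  expect_equal(independent_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(independent_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  set.seed(21)
  for (i in 1:25) {
    x <- rnorm(sample(3:40, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:40, 1), mean = runif(1, -1, 1))
    ours <- independent_t(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter))

    w <- independent_t(x, y, var_equal = FALSE)
    refw <- t.test(x, y)
    expect_equal(w$statistic, unname(refw$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(refw$parameter), tolerance = 1e-10)
  }

  expect_error(independent_t(1, c(1, 2)), "at least 2")
  deg <- independent_t(c(1, 1, 1), c(2, 2, 2))
  expect_equal(deg$p_value, 0)
  expect_match(deg$note, "zero variance")
  deg0 <- independent_t(c(1, 1, 1), c(1, 1, 1))
  expect_equal(deg0$p_value, 1)
})

test_that("paired t is the one-sample t on differences", {
  b <- c(3, 5, 8, 2, 7)
  expect_equal(paired_t(b, b)$statistic, 0)
  expect_equal(paired_t(b, b)$p_value, 1)

  set.seed(22)
  for (i in 1:25) {
    n <- sample(3:30, 1)
    before <- rnorm(n)
    after <- before + rnorm(n, 0.3)
    ours <- paired_t(before, after)
    ref <- t.test(after, before, paired = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }

  expect_error(paired_t(1:3, 1:4), "length")
  deg <- paired_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(deg$p_value, 0)
  expect_match(deg$note, "zero variance")
})

test_that("mixed ANOVA reproduces the aov error-stratum decomposition", {
  set.seed(23)
  # balanced toy
  bal <- make_mixed_data(n1 = 8, n2 = 8, delta_time = 0.5, delta_interaction = 0.7)
  ours <- mixed_anova(bal, "y")
  ref <- aov_mixed_ss(bal)
  expect_equal(ours$ss[ours$effect == "group"], ref$group, tolerance = 1e-10)
  expect_equal(ours$ss[ours$effect == "time"], ref$time, tolerance = 1e-10)
  expect_equal(ours$ss[ours$effect == "group:time"], ref$inter, tolerance = 1e-10)
  expect_equal(ours$error_ss[ours$effect == "group"], ref$subj, tolerance = 1e-10)
  expect_equal(ours$error_ss[ours$effect == "time"], ref$err, tolerance = 1e-10)

  # unbalanced arms: the interaction and within-subject strata still agree
  unb <- make_mixed_data(n1 = 7, n2 = 19, delta_interaction = 0.4)
  ours <- mixed_anova(unb, "y")
  ref <- aov_mixed_ss(unb)
  expect_equal(ours$ss[ours$effect == "group:time"], ref$inter, tolerance = 1e-10)
  expect_equal(ours$error_ss[ours$effect == "time"], ref$err, tolerance = 1e-10)
  expect_equal(ours$ss[ours$effect == "group"], ref$group, tolerance = 1e-10)
})

test_that("zero-noise equal arm trajectories give a null interaction", {
  d <- tibble::tibble(
    participant_id = rep(sprintf("S%02d", 1:6), 2),
    arm = rep(rep(c("web", "conventional"), each = 3), 2),
    timepoint = rep(c("baseline", "discharge"), each = 6),
    y = c(1:6, 1:6 + 2)  # identical +2 trajectory in both arms
  )
  res <- mixed_anova(d, "y")
  expect_equal(res$ss[res$effect == "group:time"], 0, tolerance = 1e-12)
})

test_that("interaction F equals the squared change-score t", {
  set.seed(24)
  for (i in 1:30) {
    d <- make_mixed_data(n1 = sample(3:15, 1), n2 = sample(3:25, 1),
                         delta_time = rnorm(1), delta_interaction = rnorm(1))
    res <- mixed_anova(d, "y")
    f <- res$statistic[res$effect == "group:time"]
    ch <- tidyr::pivot_wider(d, names_from = "timepoint", values_from = "y")
    ch$change <- ch$discharge - ch$baseline
    t <- independent_t(ch$change[ch$arm == "web"],
                       ch$change[ch$arm == "conventional"])$statistic
    expect_equal(f, t^2, tolerance = 1e-10)
  }
})

test_that("incomplete subjects are dropped unless strict", {
  d <- make_mixed_data(n1 = 4, n2 = 4)
  d <- d[-1, ]  # first subject loses baseline
  expect_warning(res <- mixed_anova(d, "y"), "complete-case")
  expect_error(mixed_anova(d, "y", strict = TRUE), "complete")
})

test_that("spearman uses mid-ranks and the t approximation", {
  up <- spearman_cor(1:10, (1:10)^3)
  expect_equal(up$estimate, 1)
  expect_equal(up$p_value, 0)

  hand <- spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(hand$estimate, 0.6)

  set.seed(25)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    x <- sample(1:8, n, replace = TRUE)  # heavy ties
    y <- x + sample(1:5, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    ours <- spearman_cor(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(ours$estimate, unname(ref$estimate), tolerance = 1e-12)
    # brute-force mid-rank Pearson
    expect_equal(ours$estimate, cor(rank(x), rank(y)), tolerance = 1e-12)
    if (abs(ours$estimate) < 1) {
      tt <- ours$estimate * sqrt((n - 2) / (1 - ours$estimate^2))
      expect_equal(ours$p_value, 2 * pt(-abs(tt), n - 2), tolerance = 1e-12)
    }
  }

  # invariance under strictly monotone transforms
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(spearman_cor(x, y)$estimate,
               spearman_cor(exp(x), y^3 + 5 * y)$estimate, tolerance = 1e-12)

  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("the correlation screen flags only the planted covariate", {
  set.seed(26)
  n <- 60
  cohort <- tibble::tibble(
    participant_id = sprintf("S%02d", 1:n),
    timepoint = "baseline",
    age = runif(n, 50, 85),
    bmi = rnorm(n, 28, 5),
    fev1_pct_pred = rnorm(n, 55, 20)
  )
  cohort$bouts_10 <- 10 - 0.1 * cohort$age + rnorm(n, 0, 0.5)  # planted in age only
  sc <- correlation_screen(cohort, "bouts_10")
  expect_lt(sc$p_value[sc$clinical_field == "age"], 0.05)
  expect_lt(sc$estimate[sc$clinical_field == "age"], 0)
  expect_gt(min(sc$p_value[sc$clinical_field != "age"]), 0.05)

  # per-field errors are captured, not fatal
  cohort$bouts_10 <- 1
  sc2 <- correlation_screen(cohort, "bouts_10")
  expect_true(all(is.na(sc2$estimate)))
  expect_true(all(grepl("constant", sc2$note)))

  # deterministic ordering
  expect_equal(sc$clinical_field, c("age", "bmi", "fev1_pct_pred"))
})

test_that("p-value display follows the <.001 convention", {
  expect_equal(format_p(c(0.0004, 0.034, 0.5, NA)),
               c("<.001", ".034", ".500", NA))
})
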