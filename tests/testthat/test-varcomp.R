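toy_w1 <- c(10, 20, 30, 40)
toy_w2 <- c(12, 18, 33, 37)

test_that("the toy table reproduces the hand-computed decomposition", {
  tab <- paired_table(toy_w1, toy_w2)
  v <- variance_components(tab, "x")
  expect_equal(v$ms_subject, 913 / 3, tolerance = 1e-12)
  expect_equal(v$ms_error, 13 / 3, tolerance = 1e-12)
  expect_equal(v$s2_bs, 150, tolerance = 1e-12)
  expect_equal(v$F, 0, tolerance = 1e-12)
  expect_equal(v$p_week, 1, tolerance = 1e-12)
  expect_equal(v$pearson_r, 150 / sqrt(500 / 3 * 142), tolerance = 1e-12)
  expect_false(v$separable_error)
  expect_equal(v$s2_total, v$s2_bs + v$s2_ws + v$s2_e)
})

test_that("identical weeks give r = 1, F = 0 and zero error variance", {
  tab <- paired_table(c(5, 9, 14, 20), c(5, 9, 14, 20))
  v <- variance_components(tab, "x")
  expect_equal(v$pearson_r, 1)
  expect_equal(v$F, 0)
  expect_equal(v$ms_error, 0)
  expect_equal(v$s2_bs, var(c(5, 9, 14, 20)), tolerance = 1e-12)
})

test_that("the week-effect F equals the squared paired-t statistic", {
  set.seed(314)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    w1 <- rnorm(n, 10, 3)
    w2 <- w1 + rnorm(n, 0.5, 1)
    a <- between_week_agreement(w1, w2)
    tt <- t.test(w2, w1, paired = TRUE)
    expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(a$p_week, tt$p.value, tolerance = 1e-9)
  }
})

test_that("the balanced sums of squares decompose the total exactly", {
  set.seed(99)
  w1 <- rnorm(25); w2 <- rnorm(25)
  ss <- gaitquality:::rm_anova_ss(w1, w2)
  expect_equal(ss$ss_subject + ss$ss_week + ss$ss_error, ss$ss_total,
               tolerance = 1e-12)
})

test_that("degenerate inputs are flagged", {
  expect_error(variance_components(paired_table(1:2, 2:3), "x"), "at least 3")
  expect_warning(between_week_agreement(rep(1, 5), c(1, 2, 3, 4, 5)),
                 "zero variance")
  # more error than subject variance: truncation is reported
  set.seed(1)
  tab <- paired_table(c(1, 1.01, 0.99, 1.02), c(1.5, 0.2, 1.9, 0.4))
  expect_warning(v <- variance_components(tab, "x"), "truncated")
  expect_equal(v$s2_bs, 0)
  expect_true(v$truncated)
})

test_that("day-level data separates within-subject from error variance", {
  spec <- cohort_spec(2000, mu = 5, s2_bs = 1, s2_ws = 0.3, s2_e = 0.2,
                      days_per_week = 7, seed = 8)
  sim <- simulate_cohort(spec)
  tab <- sim$weekly; names(tab)[3] <- "x"
  dl <- sim$days
  v <- variance_components(tab, "x", day_level = dl)
  expect_true(v$separable_error)
  expect_equal(v$s2_bs, 1, tolerance = 0.1)
  expect_equal(v$s2_ws, 0.3, tolerance = 0.15)
  expect_equal(v$s2_e, 0.2, tolerance = 0.15)
  # without day-level data the split is explicitly unavailable
  v0 <- variance_components(tab, "x")
  expect_false(v0$separable_error)
  expect_equal(v0$s2_ws, 0)
  expect_equal(v0$s2_e, v$s2_ws + v$s2_e, tolerance = 0.05)
})

test_that("moment estimates agree with an lme4 REML fit on a large cohort", {
  spec <- cohort_spec(5000, mu = 2, s2_bs = 0.5, s2_ws = 0, s2_e = 0.1,
                      seed = 4)
  sim <- simulate_cohort(spec)
  tab <- sim$weekly; names(tab)[3] <- "x"
  v <- variance_components(tab, "x")
  fit <- lme4::lmer(x ~ factor(week) + (1 | subject), data = tab, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2_bs_reml <- vc$vcov[vc$grp == "subject"]
  s2_e_reml <- vc$vcov[vc$grp == "Residual"]
  expect_equal(v$s2_bs, s2_bs_reml, tolerance = 0.02)
  expect_equal(v$ms_error, s2_e_reml, tolerance = 0.02)
})

test_that("median variance factors are correct where known in closed form", {
  f <- median_var_factor(c(1, 2))
  expect_equal(unname(f["1"]), 1)
  # median of two = mean of two: variance 1/2
  expect_equal(unname(f["2"]), 0.5, tolerance = 0.02)
  # factors decrease with the number of days
  f2 <- median_var_factor(c(3, 5, 7))
  expect_true(all(diff(unname(f2)) < 0))
  # deterministic across calls
  expect_identical(median_var_factor(7), median_var_factor(7))
})

test_that("varcomp reports serialize to JSON and back", {
  tab <- paired_table(toy_w1, toy_w2)
  rep1 <- varcomp_report(tab)
  path <- withr::local_tempfile(fileext = ".json")
  write_varcomp_json(rep1, path)
  back <- read_varcomp_json(path)
  expect_equal(back$x$s2_bs, rep1$x$s2_bs, tolerance = 1e-12)
  expect_equal(back$x$pearson_r, rep1$x$pearson_r, tolerance = 1e-12)
})
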