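test_that("driving performance inverts the mean absolute acceleration", {
  ts <- seq(0, 10, by = 0.1)
  ramp <- 3.6 * (0.5 * ts)                     # constant 0.5 m/s^2 in km/h
  expect_equal(as.numeric(driving_performance(ramp, ts)), 2, tolerance = 1e-9)

  saw <- 3.6 * c(2 * ts[ts <= 5], 20 - 2 * ts[ts > 5])   # |slope| = 2 m/s^2
  expect_equal(as.numeric(driving_performance(saw, ts)), 0.5, tolerance = 1e-9)
  # signed mean would be ~0 here; the absolute value is what makes this finite
  expect_equal(attr(driving_performance(saw, ts), "avg_acc"), 2, tolerance = 1e-9)

  const <- driving_performance(rep(40, length(ts)), ts)
  expect_true(attr(const, "degenerate"))

  expect_error(driving_performance(c(40, 41), c(0, 1)), "too short")
  expect_error(driving_performance(c(40, 41, 42), c(0, 2, 1)), "non-monotone")
})

test_that("the RMS acceleration variant is available and differs under variable slopes", {
  ts <- seq(0, 10, by = 0.1)
  set.seed(8)
  speed <- 40 + cumsum(rnorm(length(ts), sd = 0.3))
  p_abs <- driving_performance(speed, ts, method = "abs")
  p_rms <- driving_performance(speed, ts, method = "rms")
  expect_lt(as.numeric(p_rms), as.numeric(p_abs))   # RMS >= mean |.|
})

test_that("two-group ANOVA matches the pooled t-test identity", {
  set.seed(4)
  a <- rnorm(20, mean = 1)
  b <- rnorm(25, mean = 1.4)
  res <- anova_two_group(a, b)
  expect_identical(res$df_between, 1L)
  expect_identical(res$df_within, 43L)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$f_statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-9)

  expect_equal(anova_two_group(a, a)$f_statistic, 0, tolerance = 1e-12)
  expect_error(anova_two_group(1, a), "at least 2")
})

test_that("correlation report covers the exact and degenerate cases", {
  x <- c(1, 3, 2, 5, 4, 7, 6)
  perfect <- correlate(x, x)
  expect_equal(perfect$plcc, 1)
  expect_equal(perfect$kendall, 1)
  expect_equal(perfect$spearman, 1)
  inverse <- correlate(x, -x)
  expect_equal(inverse$plcc, -1)
  expect_equal(inverse$spearman, -1)

  expect_warning(res <- correlate(rep(1, 5), 1:5), "zero-variance")
  expect_true(res$degenerate)
  expect_true(is.na(res$plcc))
})

test_that("Spearman equals Pearson applied to average ranks, ties included", {
  set.seed(15)
  x <- round(rnorm(40), 1)                     # rounding induces ties
  y <- round(x + rnorm(40), 1)
  res <- correlate(x, y)
  expect_equal(res$spearman, cor(rank(x), rank(y)), tolerance = 1e-12)
})

test_that("cohort assembly produces the display table and both statistics", {
  te <- cohort_te(); nu <- cohort_nuid()
  trials <- data.frame(participant_id = te$participant, trial_id = te$trial,
                       te_head_to_eye = te$te_head_to_eye_x100 / 100,
                       te_eye_to_head = te$te_eye_to_head_x100 / 100,
                       nuid = nu$nuid_x100 / 100,
                       performance = nu$performance_s2_per_m)
  cohort <- assemble_cohort(trials)
  expect_equal(nrow(cohort$table), 48L)
  expect_equal(length(unique(trials$participant_id)), 12L)
  expect_equal(cohort$table$te_head_to_eye_x100, te$te_head_to_eye_x100)
  expect_identical(cohort$anova$df_within, 94L)
  expect_s3_class(cohort$correlations, "correlation_report")

  expect_warning(single <- assemble_cohort(trials[1, ]), "fewer than 3")
  expect_null(single$anova)
  expect_null(single$correlations)
})
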