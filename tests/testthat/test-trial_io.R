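test_that("well-formed trial files round-trip through write and load", {
  p1 <- write_demo_trial(withr::local_tempfile(fileext = ".tsv"))
  rec <- load_trial(p1, participant_id = "p1", trial_id = "t1")
  expect_s3_class(rec, "trial_recording")
  expect_length(rec$timestamps, 270)
  expect_equal(rec$sample_rate, 90, tolerance = 1e-6)
  expect_false(any(rec$missing_mask))

  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_trial(rec, p2)
  rec2 <- load_trial(p2, participant_id = "p1", trial_id = "t1")
  for (ch in c("timestamps", "eye_yaw", "eye_pitch", "head_yaw", "head_pitch", "speed")) {
    expect_equal(rec2[[ch]], rec[[ch]], tolerance = 1e-9, label = ch)
  }
})

test_that("unparseable rotation values are masked, never dropped", {
  p <- write_demo_trial(withr::local_tempfile(fileext = ".tsv"),
                        na_rows = c(11, 12, 200))
  rec <- load_trial(p)
  expect_length(rec$timestamps, 270)
  expect_equal(which(rec$missing_mask), c(11L, 12L, 200L))
  expect_true(all(is.na(rec$eye_yaw[c(11, 12, 200)])))
})

test_that("load_trial rejects broken inputs", {
  expect_error(load_trial(file.path(tempdir(), "does-not-exist.tsv")), "not found")

  p <- write_demo_trial(withr::local_tempfile(fileext = ".tsv"))
  expect_error(load_trial(p, schema = trial_schema(eye_yaw = "nonexistent_col")),
               "absent")

  df <- read.delim(p)
  df$time_s[10] <- df$time_s[9] - 0.5
  p_bad <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, p_bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_trial(p_bad), "non-monotone timestamps")
})

test_that("recording constructor enforces its invariants", {
  ts <- (0:9) / 90
  z <- numeric(10)
  expect_error(trial_recording(ts[1], z[1], z[1], z[1], z[1]), "at least 2")
  expect_error(trial_recording(ts, z[1:5], z, z, z), "same length")
  expect_error(trial_recording(ts, z, z, z, z, sample_rate = 50), "1%")
  expect_error(trial_recording(ts, z + 200, z, z, z), "unwrapped")
  expect_silent(trial_recording(ts, z + 200, z, z, z, unwrapped = TRUE))
})

test_that("clean_gaps fills only short interior gaps", {
  n <- 100
  ts <- (seq_len(n) - 1) / 90
  ramp <- seq(0, 2, length.out = n)
  ey <- ramp; ey[50] <- NA                      # single missing inside a ramp
  rec <- trial_recording(ts, ey, ramp, ramp, ramp)
  out <- clean_gaps(rec, max_gap = 0.1)
  expect_equal(out$eye_yaw[50], ramp[50], tolerance = 1e-12)
  expect_false(out$missing_mask[50])
  expect_equal(out$fraction_interpolated, 1 / n)

  ey2 <- ramp; ey2[30:49] <- NA                 # 20 samples = 0.222 s > 0.1 s
  rec2 <- trial_recording(ts, ey2, ramp, ramp, ramp)
  out2 <- clean_gaps(rec2, max_gap = 0.1)
  expect_true(all(out2$missing_mask[30:49]))

  rec3 <- trial_recording(ts, ramp, ramp, ramp, ramp)
  expect_identical(clean_gaps(rec3, 0.1), rec3)  # no gaps: exact identity
})

test_that("select_axis preserves pairing and drops masked rows from both channels", {
  n <- 50
  ts <- (seq_len(n) - 1) / 90
  ey <- rnorm(n); hy <- rnorm(n)
  ey[c(3, 10, 20, 30, 40)] <- NA
  rec <- trial_recording(ts, ey, numeric(n), hy, numeric(n))
  pair <- select_axis(rec, "yaw")
  expect_length(pair$eye, n - 5)
  expect_length(pair$head, n - 5)
  expect_equal(pair$head, hy[-c(3, 10, 20, 30, 40)])

  pitch <- select_axis(rec, "pitch")
  expect_length(pitch$eye, n - 5)
  expect_error(select_axis(rec, "roll"))
})
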