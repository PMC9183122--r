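test_that("generic CSV recordings parse with the rate inferred from spacing", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,ax,ay,az",
               "0,0.1,0.2,1.0",
               sprintf("%.10f,0.2,0.3,1.1", 1 / 15),
               sprintf("%.10f,0.3,0.4,1.2", 2 / 15)), f)
  rec <- read_recording(f)
  expect_equal(nrow(rec$samples), 3L)
  expect_equal(rec$sampling_rate, 15, tolerance = 1e-6)
  expect_equal(unname(rec$samples[, "ax"]), c(0.1, 0.2, 0.3))
})

test_that("the clemson dialect fixes the sampling rate at 15 Hz", {
  f <- withr::local_tempfile(fileext = ".csv")
  t <- (0:29) / 15
  writeLines(sprintf("%.8f,%.4f,%.4f,%.4f", t, sin(t), cos(t), 1 + 0 * t), f)
  rec <- read_recording(f, dialect = "clemson")
  expect_equal(rec$sampling_rate, 15)
  expect_equal(nrow(rec$samples), 30L)
})

test_that("a dialect file can rescale m/s^2 recordings into g", {
  d <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(header = TRUE, sep = ",",
                        columns = list(t = 1, ax = 2, ay = 3, az = 4),
                        scale_to_g = 9.80665, sampling_rate = 50), d)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,ax,ay,az", "0,0,0,9.80665", "0.02,0,0,9.80665"), f)
  rec <- read_recording(f, dialect = "generic_csv", dialect_file = d)
  expect_equal(unname(rec$samples[1, ]), c(0, 0, 1))
  expect_equal(rec$sampling_rate, 50)
})

test_that("write/read round-trip preserves samples and rate", {
  sim <- simulate_subject(gait_params(duration = 5, seed = 3))
  rec <- sim$recording$recording
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, f)
  back <- read_recording(f, subject_id = rec$subject_id)
  expect_lt(max(abs(back$samples - rec$samples)), 1e-9)
  expect_equal(back$sampling_rate, rec$sampling_rate)
})

test_that("malformed and non-uniform files are rejected with useful errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,ax,ay,az", "0,0.1,0.2,1.0", "0.066,oops,0.3,1.1"), f)
  expect_error(read_recording(f), "non-numeric")

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,ax,ay,az", "0,0,0,1", "0.066,0,0,1", "0.30,0,0,1"), g)
  expect_error(read_recording(g), "non-uniform")

  expect_error(read_recording("/nonexistent/file.csv"), "not found")
})

test_that("annotation files round-trip", {
  ann <- step_annotation(c(0, 0.5, 1.1), c("L", "R", "L"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_annotation(ann, f)
  back <- read_annotation(f)
  expect_equal(back$timestamps, ann$timestamps)
  expect_equal(back$labels, ann$labels)
})

test_that("resampling a constant signal preserves it and the duration", {
  rec <- accel_recording(matrix(c(0, 0, 1), 501, 3, byrow = TRUE), 50)
  out <- resample_recording(rec, 15)
  expect_equal(out$sampling_rate, 15)
  expect_equal(nrow(out$samples), 151L)  # 10 s at 15 Hz
  expect_lt(max(abs(sweep(out$samples, 2, c(0, 0, 1)))), 1e-9)
  expect_lt(abs(rec_duration(out) - rec_duration(rec)), 1 / 15)
})

test_that("a walking-band sinusoid survives 50 -> 15 Hz within 0.01 g", {
  t50 <- (0:500) / 50
  x <- cbind(sin(2 * pi * t50), 0 * t50, 1 + 0 * t50)
  rec <- accel_recording(x, 50)
  out <- resample_recording(rec, 15)
  t15 <- (seq_len(nrow(out$samples)) - 1) / 15
  expect_lt(max(abs(out$samples[, 1] - sin(2 * pi * t15))), 0.01)
  expect_lt(max(abs(out$samples[, 3] - 1)), 0.01)
})

test_that("down-then-up resampling round-trips band-limited signals", {
  for (f_hz in c(0.5, 1, 2)) {
    t50 <- (0:1000) / 50
    rec <- accel_recording(cbind(sin(2 * pi * f_hz * t50), 0 * t50,
                                 1 + 0 * t50), 50)
    back <- resample_recording(resample_recording(rec, 15), 50)
    n <- nrow(back$samples)
    expect_lt(max(abs(back$samples[, 1] - sin(2 * pi * f_hz * t50[1:n]))),
              0.01)
  }
})

test_that("resampling refuses a single-sample recording", {
  rec <- accel_recording(matrix(c(0, 0, 1), 1, 3), 50)
  expect_error(resample_recording(rec, 15), "fewer than 2")
})

test_that("annotation alignment carries the last step side forward", {
  # events exactly on sample timestamps are copied verbatim
  rec <- tiny_recording(4, rate = 2)
  ann <- step_annotation(c(0, 0.5, 1.0, 1.5), c("L", "R", "R", "L"))
  expect_equal(align_annotation(rec, ann)$labels, c("L", "R", "R", "L"))

  # a single event labels everything after the trim
  lr1 <- align_annotation(tiny_recording(30), step_annotation(0.5, "R"))
  expect_true(all(lr1$labels == "R"))
  expect_lte(nrow(lr1$recording$samples), 30)

  # events at 0.0 s (L) and 1.0 s (R) on a 15 Hz recording
  lr2 <- align_annotation(tiny_recording(30),
                          step_annotation(c(0, 1), c("L", "R")))
  expect_equal(lr2$labels, c(rep("L", 15), rep("R", 15)))

  expect_error(
    align_annotation(tiny_recording(15), step_annotation(99, "L")),
    "no overlap")
})

test_that("alignment output is trimmed, never longer, and stays binary", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    rec <- tiny_recording(n, rate = 15, seed = i)
    k <- sample(1:5, 1)
    ts <- sort(runif(k, -0.5, n / 15))
    ts <- ts + seq_len(k) * 1e-6
    ann <- step_annotation(ts, sample(c("L", "R"), k, replace = TRUE))
    lr <- align_annotation(rec, ann)
    expect_lte(nrow(lr$recording$samples), n)
    expect_true(all(lr$labels %in% c("L", "R")))
  }
})
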