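# ECG reading, R-peak detection, R-R cleaning and tachogram resampling.

test_that("read_ecg infers the sampling rate and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,voltage", "0.000,0.1", "0.005,0.2"), f)
  rec <- read_ecg(f)
  expect_s3_class(rec, "ecg_record")
  expect_equal(rec$fs, 200)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("time_s,voltage", empty)
  expect_error(read_ecg(empty), "parse error")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,voltage", "0.000,0.1", "0.000,0.2", "0.005,0.3"), dup)
  expect_error(read_ecg(dup), "format error")

  jit <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,voltage", "0.000,0.1", "0.005,0.2", "0.012,0.3"), jit)
  expect_error(read_ecg(jit), "non-uniform")
})

test_that("read_ecg parses the wfdb-style record directory and annotations", {
  d <- withr::local_tempdir()
  writeLines(c("fs: 200", "t0: 0"), file.path(d, "header.txt"))
  utils::write.csv(data.frame(voltage = sin(1:100)), file.path(d, "signal.csv"),
                   row.names = FALSE)
  ann <- file.path(d, "ann.csv")
  utils::write.csv(data.frame(label = c("rest_start", "end"), time_s = c(0, 0.4)),
                   ann, row.names = FALSE)
  rec <- read_ecg(d, format = "wfdb", annotations = ann)
  expect_equal(rec$fs, 200)
  expect_equal(nrow(rec$annotations), 2)
})

test_that("R peaks are recovered from clean and noisy synthetic ECG", {
  truth <- 1:12
  rec <- synthesize_ecg(truth, fs = 200)
  pk <- detect_r_peaks(rec)
  expect_equal(length(pk$times), length(truth))
  expect_true(all(abs(pk$times - truth) <= 0.010))

  # 5-minute record at 20 dB peak SNR: >= 99% of beats within +/- 20 ms
  p <- default_profiles()$control
  rr <- simulate_rr(p, state_plan(), seed = 11)
  bt <- attr(rr, "beat_times")
  noisy <- synthesize_ecg(bt, fs = 200, noise_sd = 0.1, seed = 12)
  det <- detect_r_peaks(noisy)$times
  err <- vapply(bt, function(b) min(abs(det - b)), numeric(1))
  expect_gte(mean(err <= 0.020), 0.99)

  expect_error(detect_r_peaks(ecg_record(rep(0, 4000), fs = 200)), "flat-line")
})

test_that("rr_from_peaks converts peak times to intervals", {
  rr <- rr_from_peaks(c(0, 1, 2))
  expect_equal(rr$intervals, c(1000, 1000))
  expect_equal(rr$onsets, c(0, 1))
  expect_true(all(rr$flags == "accepted"))
  expect_equal(rr_from_peaks(c(0, 0.8))$intervals, 800)
  expect_error(rr_from_peaks(1.5), "at least 2")
})

test_that("clean_rr replaces isolated artifacts and drops edge artifacts", {
  rr <- rr_series(c(800, 2000, 820), c(0, 0.8, 2.8))
  cl <- clean_rr(rr)
  expect_equal(cl$intervals, c(800, 810, 820))
  expect_equal(cl$flags, c("accepted", "replaced", "accepted"))

  ok <- rr_series(c(800, 810, 820), c(0, 0.8, 1.61))
  expect_equal(clean_rr(ok)$intervals, ok$intervals)
  expect_true(all(clean_rr(ok)$flags == "accepted"))

  bad <- rr_series(c(800, 1600, 1700, 820), c(0, 0.8, 2.4, 4.1))
  expect_error(clean_rr(bad), "consecutive")

  edge <- rr_series(c(2000, 800, 820), c(0, 2, 2.8))
  cle <- clean_rr(edge)
  expect_equal(cle$intervals, c(800, 820))
  expect_equal(nrow(attr(cle, "excluded")), 1)
})

test_that("clean_rr is idempotent and preserves length up to edge drops", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    iv <- runif(n, 600, 1000)
    out_idx <- sort(sample(seq(2, n - 1), sample(0:3, 1)))
    if (length(out_idx) > 1) out_idx <- out_idx[c(TRUE, diff(out_idx) > 1)]
    iv[out_idx] <- sample(c(150, 1800), length(out_idx), replace = TRUE)
    rr <- rr_series(iv, cumsum(c(0, iv[-n])) / 1000)
    cl <- clean_rr(rr)
    expect_equal(length(cl$intervals), n)
    expect_equal(sum(cl$flags == "replaced"), length(out_idx))
    cl2 <- clean_rr(cl)
    expect_identical(cl2$intervals, cl$intervals)
    expect_identical(cl2$flags, cl$flags)
  }
})

test_that("tachogram resampling runs at the mean heart rate", {
  rr <- rr_series(rep(1000, 60), 0:59)
  tach <- resample_tachogram(rr)
  expect_equal(tach$rate, 1.0)
  expect_equal(length(tach$values), 60)
  expect_true(all(tach$values == 1000))

  rr2 <- rr_series(rep(500, 120), seq(0, by = 0.5, length.out = 120))
  tach2 <- resample_tachogram(rr2)
  expect_equal(tach2$rate, 2.0)
  expect_true(all(abs(tach2$values - 500) < 1e-9))

  expect_error(resample_tachogram(rr_series(rep(1000, 10), 0:9)),
               "insufficient data")
})

test_that("resampling preserves the variance of a slow sinusoid", {
  rr_fun <- function(t) 1000 + 50 * sin(2 * pi * 0.1 * t)
  beats <- beats_from_rr_curve(rr_fun, 300)
  rr <- rr_from_peaks(beats)
  tach <- resample_tachogram(rr)
  expect_lt(abs(stats::var(tach$values) - 1250) / 1250, 0.05)
  expect_lt(abs(mean(tach$values) - 1000) / 1000, 0.001)
})

test_that("R-R round trips: simulator beat times reproduce the interval sequence", {
  p <- default_profiles()$PPD
  rr <- simulate_rr(p, state_plan(), seed = 21)
  bt <- attr(rr, "beat_times")
  expect_equal(rr_from_peaks(bt)$intervals, rr$intervals)
  f <- withr::local_tempfile(fileext = ".csv")
  write_rr(rr, f)
  back <- read_rr(f)
  expect_equal(back$intervals, rr$intervals, tolerance = 1e-5)
})
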