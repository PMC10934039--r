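# State segmentation, settling-skip averaging, response ratios, the
# 12-entry feature vector and screening bookkeeping.

test_that("segment_states slices the trend by half-open state intervals", {
  tr <- make_trend(seq(30, 220, by = 2), lf = 100, hf = 200)
  sl <- segment_states(tr, state_plan())
  expect_named(sl, c("Rest", "Task", "After"))
  expect_true(all(sl$Rest$t < 60))
  # a frame exactly on a boundary belongs to the later state
  expect_true(60 %in% sl$Task$t && !(60 %in% sl$Rest$t))
  expect_true(160 %in% sl$After$t && !(160 %in% sl$Task$t))
  expect_equal(range(sl$Task$t), c(60, 158))
  expect_equal(max(sl$After$t), 220)

  short <- make_trend(seq(30, 150, by = 2), lf = 1, hf = 1)
  expect_error(segment_states(short, state_plan()), "coverage")
})

test_that("state_average applies the 30-s settling skip exactly", {
  tr <- make_trend(seq(30, 220, by = 2), lf = 5, hf = 10)
  a <- state_average(tr, 0, 60)
  expect_equal(a$lf, 5)
  expect_equal(a$hf, 10)

  # step at start + 30: only post-step frames enter the average
  stepped <- make_trend(seq(30, 220, by = 2),
                        lf = ifelse(seq(30, 220, by = 2) <= 90, 1, 2), hf = 1)
  expect_equal(state_average(stepped, 60, 160)$lf, 2)

  # Task state: averaging window (90, 160] holds exactly 35 frames
  expect_equal(sum(tr$t > 90 & tr$t <= 160), 35)
  expect_error(state_average(tr, 0, 25), "settling")
  expect_error(state_average(make_trend(seq(30, 58, 2), 1, 1), 60, 160),
               "insufficient")
})

test_that("averages of a state-wise constant trend reproduce the constants and ratios", {
  # a frame at t carries data from (t - 30, t], so frames up to t = 60 hold
  # pure Rest data, up to 160 Task data, beyond that After data
  t <- seq(30, 220, by = 2)
  hf <- ifelse(t <= 60, 8, ifelse(t <= 160, 4, 12))
  lf <- ifelse(t <= 60, 10, ifelse(t <= 160, 20, 5))
  tr <- make_trend(t, lf = lf, hf = hf, hr = 60)
  # constants only hold after each state's own settling skip window
  avg <- state_averages(tr, state_plan())
  expect_equal(avg$Task$hf, 4)
  expect_equal(avg$After$lf, 5)
  r <- response_ratios(avg)
  expect_equal(r$task_rest$hf, 0.5)
  expect_equal(r$after_rest$hf, 1.5)
  expect_equal(r$task_rest$lf, 2)
  expect_equal(r$after_rest$hr, 1)

  fv <- build_features(avg, r)
  expect_named(fv, FEATURE_NAMES)
  expect_equal(unname(fv["hf_rest"]), 8)
  expect_equal(unname(fv[1]), 8)     # first entry is the Rest HF level
  expect_equal(unname(fv[10]), 60)   # tenth entry is the Rest heart rate
  expect_equal(unname(fv["lf_task_rest"]), 2)
})

test_that("the averaging window never includes frames from the preceding state", {
  # trend value identifies the state that generated each frame
  t <- seq(30, 220, by = 2)
  origin <- ifelse(t <= 90, 1, ifelse(t <= 160, 2, ifelse(t <= 190, 2.5, 3)))
  tr <- make_trend(t, lf = origin, hf = 1)
  avg <- state_averages(tr, state_plan())
  # frames with any pre-Task data (t <= 90) are excluded from Task
  expect_equal(avg$Task$lf, 2)
  expect_equal(avg$After$lf, 3)
})

test_that("response_ratios guards against zero Rest averages", {
  t <- seq(30, 220, by = 2)
  tr <- make_trend(t, lf = 1, hf = c(rep(0, 16), rep(1, 80)))
  avg <- state_averages(tr, state_plan())
  expect_error(response_ratios(avg), "hf")
})

test_that("ratio identities: After equal to Rest gives a unit ratio", {
  tr <- make_trend(seq(30, 220, by = 2), lf = 3, hf = 2, hr = 72)
  r <- response_ratios(state_averages(tr, state_plan()))
  expect_equal(r$after_rest$lf, 1)
  expect_equal(r$task_rest$hr, 1)
})

test_that("breathing-band validity check uses the inclusive 9-24/min range", {
  expect_equal(check_respiration(15), "valid")
  expect_equal(check_respiration(9), "valid")
  expect_equal(check_respiration(24), "valid")
  expect_warning(out <- check_respiration(8), "9-24")
  expect_equal(out, "out_of_band")
  expect_error(check_respiration(0), "positive")
})

test_that("EPDS screening uses the >= 9 cutoff and validates range", {
  expect_equal(epds_screen(9), "positive")
  expect_equal(epds_screen(8), "negative")
  expect_equal(epds_screen(30), "positive")
  expect_error(epds_screen(31), "0, 30")
  expect_error(epds_screen(-1), "0, 30")
  expect_equal(epds_screen(12, cutoff = 13), "negative")
})

test_that("cohort accounting reproduces screening percentages", {
  subjects <- data.frame(group = c(rep("PPD", 12), rep("AJD", 33)),
                         epds = rep(10, 45))
  cs <- cohort_summary(subjects, n_screened = 935)
  expect_equal(cs$enrolled_pct, 4.8)
  expect_equal(cs$counts$pct_of_cohort[cs$counts$group == "PPD"], 26.7)
  expect_equal(cs$counts$pct_of_cohort[cs$counts$group == "AJD"], 73.3)
  # labeled-group percentages partition the cohort
  expect_equal(sum(cs$counts$pct_of_cohort), 100)
  expect_error(cohort_summary(data.frame(group = "case")), "unknown group")
})

test_that("cohort_summary tabulates per-group feature means and s.d.", {
  subjects <- data.frame(group = rep(c("control", "PPD"), each = 3),
                         hf_rest = c(1, 2, 3, 10, 20, 30),
                         hf_task_rest = 1)
  cs <- cohort_summary(subjects)
  expect_equal(cs$features$control$mean[cs$features$control$feature == "hf_rest"], 2)
  expect_equal(cs$features$PPD$sd[cs$features$PPD$feature == "hf_rest"], 10)
})

test_that("half-up rounding follows the reporting convention", {
  expect_equal(round_half_up(26.65, 1), 26.7)
  expect_equal(round_half_up(84.615, 1), 84.6)
  expect_equal(round_half_up(90.9090, 1), 90.9)
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(-2.5, 0), -3)
})
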