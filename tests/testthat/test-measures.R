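t0 <- as.POSIXct("2024-05-01 09:00:00", tz = "UTC")

grid_times <- function(n) t0 + seq(0, by = 10, length.out = n)

test_that("detect_bouts reproduces the hand-traced worked fixtures", {
  fx <- make_worked_fixtures()
  b <- detect_bouts(fx$minimal_bout$epoch_start, fx$minimal_bout$steps)
  expect_equal(nrow(b), 1L)
  expect_equal(b$duration, 30)
  expect_equal(b$n_walk_epochs, 3L)

  ## two qualifying epochs: below the 3-epoch minimum
  expect_equal(nrow(detect_bouts(grid_times(2), c(8L, 9L))), 0L)

  b <- detect_bouts(fx$bridged_gap$epoch_start, fx$bridged_gap$steps)
  expect_equal(nrow(b), 1L)
  expect_equal(b$duration, 60)
  expect_equal(b$n_walk_epochs, 4L)

  b <- detect_bouts(fx$split_gap$epoch_start, fx$split_gap$steps)
  expect_equal(nrow(b), 1L)  # isolated head epoch discarded
  expect_equal(b$duration, 30)
  expect_equal(as.numeric(b$start - fx$split_gap$epoch_start[1]), 40)
})

test_that("detect_bouts enforces its input contract", {
  expect_error(detect_bouts(t0 + c(10, 0, 20), c(8L, 8L, 8L)), "increasing")
  expect_error(detect_bouts(t0 + c(0, 15), c(8L, 8L)), "grid")
})

test_that("detect_bouts agrees with the brute-force scan oracle", {
  set.seed(101)
  for (rep in 1:400) {
    day <- random_epoch_day(n_slots = sample(5:120, 1),
                            p_present = runif(1, 0.5, 1))
    got <- detect_bouts(day$t, day$steps)
    want <- oracle_bouts(day$t, day$steps)
    expect_equal(nrow(got), nrow(want))
    expect_equal(as.numeric(got$start), want$start)
    expect_equal(as.numeric(got$end), want$end)
    expect_equal(got$n_walk_epochs, want$n_walk_epochs)
    expect_equal(got$duration, want$duration)
  }
})

test_that("gaps of <= 20 s never split a bout; >= 30 s always do", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(6:30, 1)
    steps <- rep(10L, n)
    t <- grid_times(n)
    base <- detect_bouts(t, steps)
    expect_equal(nrow(base), 1L)
    cut <- sample(seq(3L, n - 3L), 1)  # both pieces keep >= 3 qualifying epochs
    if (n == 6L) cut <- 3L  # sample() treats a length-1 vector as 1:x
    for (gap_epochs in 1:2) {  # 10 s and 20 s interruptions
      s2 <- steps; s2[cut + seq_len(gap_epochs)] <- 0L
      expect_equal(nrow(detect_bouts(t, s2)), 1L)
    }
    s3 <- c(steps[1:cut], rep(0L, 3L), steps[(cut + 1):n])
    expect_equal(nrow(detect_bouts(grid_times(n + 3L), s3)), 2L)
  }
})

test_that("peak30_cadence matches the sort-and-sum oracle and ignores order", {
  expect_equal(peak30_cadence(rep(20L, 180)), 2)
  expect_equal(peak30_cadence(c(rep(20L, 180), rep(0L, 500))), 2)
  expect_equal(peak30_cadence(rep(0L, 1000)), 0)
  expect_equal(peak30_cadence(integer(0)), 0)
  ## fewer than 180 epochs: implicit zero padding
  expect_equal(peak30_cadence(rep(30L, 90)), 30 * 90 / 1800)
  set.seed(5)
  steps <- sample(0:40, 200, replace = TRUE)
  want <- sum(sort(steps, decreasing = TRUE)[1:180]) / 1800
  expect_equal(peak30_cadence(steps), want)
  expect_equal(peak30_cadence(sample(steps)), want)
})

test_that("peak30_pace applies the gender- and height-based step length", {
  expect_equal(unname(peak30_pace(2, "male", 1.70)), 2 * 0.415 * 1.70)
  expect_equal(unname(peak30_pace(0, "female", 1.55)), 0)
  expect_equal(unname(peak30_pace(1.5, "female", 1.80)),
               2 * unname(peak30_pace(1.5, "female", 0.90)))
  expect_true(is.na(peak30_pace(2, "male", NA_real_)))
  expect_equal(unname(peak30_pace(2, "unspecified", 1)), 2 * 0.414)
})

test_that("daily_measures handles empty, minimal and long-bout days", {
  empty <- data.table::data.table(
    epoch_start = t0[0], steps = integer(0), worn = logical(0))
  dm <- daily_measures(empty)
  expect_equal(dm$step_count, 0L)
  expect_equal(dm$n_bouts, 0L)
  expect_true(is.na(dm$bout_duration_mean))
  expect_true(is.na(dm$bout_duration_sd))
  expect_true(is.na(dm$bout_duration_p95))
  expect_equal(dm$peak30_cadence, 0)

  one_bout <- data.table::data.table(
    epoch_start = grid_times(3), steps = c(8L, 9L, 7L), worn = TRUE)
  dm <- daily_measures(one_bout, gender = "male", height_m = 1.70)
  expect_equal(dm$n_bouts, 1L)
  expect_equal(dm$n_short_bouts, 1L)
  expect_equal(dm$n_long_bouts, 0L)
  expect_equal(dm$bout_duration_mean, 30)
  expect_true(is.na(dm$bout_duration_sd))  # single bout
  expect_equal(dm$step_count, 24L)
  expect_equal(dm$ambulatory_time, 30 / 3600)

  ## a 130-s bout is long, not short
  long_day <- data.table::data.table(
    epoch_start = grid_times(13), steps = rep(8L, 13), worn = TRUE)
  dm <- daily_measures(long_day)
  expect_equal(dm$n_bouts, 1L)
  expect_equal(dm$n_short_bouts, 0L)
  expect_equal(dm$n_long_bouts, 1L)
  expect_equal(dm$bout_duration_mean, 130)

  ## a 90-s bout belongs to neither class
  mid_day <- data.table::data.table(
    epoch_start = grid_times(9), steps = rep(8L, 9), worn = TRUE)
  dm <- daily_measures(mid_day)
  expect_equal(dm$n_bouts, 1L)
  expect_equal(dm$n_short_bouts + dm$n_long_bouts, 0L)
})

test_that("daily measure invariants hold on random simulated days", {
  sim <- simulate_cohort(cohort_config(n_participants = 5L, n_days = 3L,
                                       seed = 3L))
  daily <- compute_daily_measures(sim$epochs, sim$meta)
  expect_true(all(daily$n_short_bouts + daily$n_long_bouts <= daily$n_bouts))
  expect_true(all(daily$peak30_cadence <= 6))
  expect_true(all(daily$wear_time <= 24))
  ## time in bout epochs never exceeds ambulatory (qualifying-epoch) time
  ep <- sim$epochs[device == "study"]
  ep[, date := as.Date(epoch_start, tz = "UTC")]
  chk <- ep[, {
    b <- detect_bouts(epoch_start, steps)
    .(bout_walk_h = sum(b$n_walk_epochs) * 10 / 3600)
  }, by = .(participant_id, date)]
  joined <- daily[device == "study"][chk, on = c("participant_id", "date")]
  expect_true(all(joined$bout_walk_h <= joined$ambulatory_time + 1e-12))
  ## step count is at least the steps inside bouts
  expect_true(all(daily$step_count >= 0))
})

test_that("bout_duration_p95 is the linear-interpolation empirical quantile", {
  expect_true(is.na(bout_duration_p95(numeric(0))))
  expect_equal(bout_duration_p95(50), 50)
  d <- c(30, 40, 50, 60, 200)
  expect_equal(bout_duration_p95(d), unname(quantile(d, 0.95, type = 7)))
  expect_equal(bout_duration_p95(d, type = 1),
               unname(quantile(d, 0.95, type = 1)))
})

test_that("filter_accuracy_days applies the wear and step thresholds", {
  fx <- make_worked_fixtures()
  daily <- compute_daily_measures(fx$low_wear_day)
  expect_equal(daily[device == "study", wear_time], 7.9)
  expect_equal(nrow(filter_accuracy_days(daily)), 0L)

  daily <- compute_daily_measures(fx$exact_100_steps)
  expect_equal(unique(daily$step_count), 100L)
  expect_true(all(daily$wear_time >= 8))
  expect_equal(nrow(filter_accuracy_days(daily)), 0L)  # strict > 100

  ## 5 paired days, 2 violating (one low wear, one low steps) -> 3 retained
  mk <- function(dev, wear, steps)
    data.table::data.table(participant_id = "p1", device = dev,
                           date = as.Date("2024-05-01") + 0:4,
                           step_count = steps, wear_time = wear)
  daily <- rbind(mk("study", c(9, 7.9, 9, 9, 9), c(5000, 5000, 100, 5000, 5000)),
                 mk("reference", rep(9, 5), rep(5000, 5)))
  kept <- filter_accuracy_days(daily)
  expect_equal(nrow(kept), 6L)  # 3 days x 2 devices
  expect_identical(sort(unique(kept$date)),
                   as.Date("2024-05-01") + c(0, 3, 4))
  ## a day present on only one device is dropped
  solo <- rbind(mk("study", rep(9, 5), rep(5000, 5)))
  expect_equal(nrow(filter_accuracy_days(solo)), 0L)
})

test_that("daily measures survive a CSV round trip with empty-cell nulls", {
  sim <- simulate_cohort(cohort_config(n_participants = 3L, n_days = 2L,
                                       seed = 9L))
  daily <- compute_daily_measures(sim$epochs, sim$meta)
  f <- tempfile(fileext = ".csv")
  write_daily_measures(daily, f)
  back <- read_daily_measures(f)
  expect_equal(back, daily, ignore_attr = TRUE)
})
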