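daily_table <- function(participant_id, dates, wear, steps) {
  data.table::data.table(participant_id = participant_id, date = dates,
                         wear_time = wear, step_count = steps)
}

test_that("eligible_participants applies the span and wear-fraction rules", {
  full <- daily_table("p1", as.Date("2024-01-01") + 0:59, 13, 8000)
  for (k in c(1L, 7L, 30L)) {
    el <- eligible_participants(full, k)
    expect_true("p1" %in% el$participant_id)
    expect_equal(min(el$start_offset), 0L)
    expect_equal(max(el$start_offset), 60L - 2L * k)
  }
  one_day <- daily_table("p2", as.Date("2024-01-01"), 13, 8000)
  expect_equal(nrow(eligible_participants(one_day, 1L)), 0L)

  ## k = 4 with exactly 2 of 4 valid days per window: the >= 50% boundary
  wear <- c(13, 13, 5, 5, 13, 13, 5, 5)
  border <- daily_table("p3", as.Date("2024-01-01") + 0:7, wear, 8000)
  expect_true("p3" %in% eligible_participants(border, 4L)$participant_id)
  ## one valid day fewer in window B -> ineligible
  wear[5] <- 5
  border2 <- daily_table("p3", as.Date("2024-01-01") + 0:7, wear, 8000)
  el <- eligible_participants(border2, 4L)
  expect_false(any(el$start_offset == 0L))
})

test_that("window_means averages valid days in adjacent windows", {
  d2 <- daily_table("p1", as.Date("2024-01-01") + 0:1, 13, c(8000, 9000))
  expect_equal(window_means(d2, "p1", 1L, 0L, "step_count"),
               c(mean_a = 8000, mean_b = 9000))
  d4 <- daily_table("p1", as.Date("2024-01-01") + 0:3, 13,
                    c(100, 200, 300, 500))
  expect_equal(window_means(d4, "p1", 2L, 0L, "step_count"),
               c(mean_a = 150, mean_b = 400))
  ## a sub-12 h day inside window A is excluded from the mean
  d6 <- daily_table("p1", as.Date("2024-01-01") + 0:5,
                    c(13, 5, 13, 13, 13, 13), c(100, 999, 200, 300, 400, 500))
  expect_equal(window_means(d6, "p1", 3L, 0L, "step_count"),
               c(mean_a = 150, mean_b = 400))
  ## window with zero valid days -> NA
  d0 <- daily_table("p1", as.Date("2024-01-01") + 0:1, c(13, 5), c(1, 2))
  expect_true(is.na(window_means(d0, "p1", 1L, 0L, "step_count")[["mean_b"]]))
})

test_that("adjacent_window_icc hits the degenerate-variance limits", {
  ## constant within participant, distinct between participants -> ICC 1
  const <- data.table::rbindlist(lapply(1:6, function(i)
    daily_table(sprintf("p%d", i), as.Date("2024-01-01") + 0:9, 13,
                1000 * i)))
  for (k in c(1L, 3L)) {
    res <- adjacent_window_icc(const, k, "step_count", n_boot = 0L)
    expect_equal(res$icc, 1)
    expect_equal(res$n_participants, 6L)
  }
  ## i.i.d. across participants and days -> ICC near 0
  set.seed(19)
  iid <- data.table::rbindlist(lapply(1:150, function(i)
    daily_table(sprintf("p%03d", i), as.Date("2024-01-01") + 0:5, 13,
                rnorm(6, 8000, 1000))))
  res <- adjacent_window_icc(iid, 3L, "step_count", n_boot = 0L)
  expect_lt(abs(res$icc), 0.15)
  ## fewer than 2 eligible participants -> undefined
  res <- adjacent_window_icc(const[participant_id == "p1"], 1L,
                             "step_count", n_boot = 0L)
  expect_true(is.na(res$icc))
})

test_that("the reliability curve follows the Spearman-Brown form", {
  dt <- simulate_daily_cohort(150, 24, between_sd = 3, within_sd = 3,
                              mean_daily_steps = 10, seed = 23)
  for (k in c(1L, 3L, 6L)) {
    res <- adjacent_window_icc(dt, k, "step_count", n_boot = 100L, seed = 2L)
    theory <- 9 / (9 + 9 / k)
    se <- (res$ci_high - res$ci_low) / (2 * 1.96)
    expect_lt(abs(res$icc - theory), 3 * pmax(se, 0.01))
    expect_true(res$ci_low <= res$icc && res$icc <= res$ci_high)
  }
})

test_that("day-level white noise lowers the curve at every scope", {
  base <- simulate_daily_cohort(120, 16, between_sd = 3, within_sd = 2,
                                mean_daily_steps = 100, seed = 31)
  noisy <- data.table::copy(base)
  set.seed(32)
  noisy[, step_count := step_count + rnorm(.N, 0, 4)]
  for (k in c(1L, 4L)) {
    icc_base <- adjacent_window_icc(base, k, "step_count", n_boot = 0L)$icc
    icc_noisy <- adjacent_window_icc(noisy, k, "step_count", n_boot = 0L)$icc
    expect_gt(icc_base, icc_noisy)
  }
})

test_that("cohort size is non-increasing in the aggregation scope", {
  set.seed(41)
  ## ragged spans and imperfect wear so eligibility actually tightens
  dt <- data.table::rbindlist(lapply(1:25, function(i) {
    n <- sample(4:40, 1)
    daily_table(sprintf("p%02d", i), as.Date("2024-01-01") + 0:(n - 1),
                sample(c(5, 13), n, replace = TRUE, prob = c(0.3, 0.7)),
                rnorm(n, 9000, 2000))
  }))
  curve <- reliability_curve(dt, measures = "step_count", scopes = 1:10,
                             n_boot = 0L)
  expect_true(all(diff(curve$n_participants) <= 0L))
})

test_that("time_to_reliability returns the first threshold crossing", {
  expect_equal(time_to_reliability(c(0.5, 0.7, 0.76, 0.8)), 3L)
  expect_true(is.na(time_to_reliability(c(0.5, 0.6, 0.7))))
  expect_equal(time_to_reliability(c(0.8, 0.9)), 1L)
  expect_equal(time_to_reliability(c(0.7, 0.76, NA, 0.8),
                                   scope = c(1, 4, 2, 8)), 4L)
  expect_equal(time_to_reliability(c(0.5, 0.9), threshold = 0.9), 2L)
})

test_that("reliability_curve is deterministic and excludes pace by default", {
  sim <- simulate_cohort(cohort_config(n_participants = 6L, n_days = 8L,
                                       seed = 13L, wear_start = 6,
                                       wear_end = 20.5))
  daily <- compute_daily_measures(sim$epochs, sim$meta)[device == "study"]
  c1 <- reliability_curve(daily, scopes = 1:3, n_boot = 30L, seed = 4L)
  c2 <- reliability_curve(daily, scopes = 1:3, n_boot = 30L, seed = 4L)
  expect_identical(c1, c2)
  expect_false("peak30_pace" %in% c1$measure)
  expect_true("peak30_cadence" %in% c1$measure)
  ttr <- attr(c1, "time_to_reliability")
  expect_setequal(ttr$measure, unique(c1$measure))
})
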