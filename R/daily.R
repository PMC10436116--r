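## Daily walking measures computed from one device's epoch stream.
##
## Nine measures per participant-day-device (Table: walking_measures()),
## plus wear time and ambulatory time used by downstream filters.

## Anthropometric step-length fractions of body height, by gender.  The
## pace conversion is step length x cadence; these multipliers are the
## conventional values and are configurable in peak30_pace().
.WW_STEP_LENGTH_K <- c(female = 0.413, male = 0.415, unspecified = 0.414)

#' Peak 30-minute cadence of a day
#'
#' Mean cadence (steps/second) over the day's 180 highest-count 10-second
#' epochs (30 minutes, not necessarily contiguous).  Days with fewer than
#' 180 recorded epochs are implicitly zero-padded so the denominator is
#' always 1800 s.
#'
#' @param steps Integer epoch step counts for one participant-day-device.
#' @param n_top Number of epochs in the peak window (default 180).
#' @param grid_seconds Epoch grid in seconds (default 10).
#' @return Cadence in steps/second.
#' @export
#' @examples
#' peak30_cadence(rep(20L, 180))  # 2 steps/s
peak30_cadence <- function(steps, n_top = 180L, grid_seconds = 10L) {
  if (length(steps) == 0L) return(0)
  top <- sort(steps, decreasing = TRUE)
  sum(head(top, n_top)) / (n_top * grid_seconds)
}

#' Convert peak cadence to peak pace via estimated step length
#'
#' Pace = cadence x step length, with step length estimated as a
#' gender-specific fraction of body height.
#'
#' @param cadence Steps/second (e.g. from [peak30_cadence()]).
#' @param gender `"female"`, `"male"` or `"unspecified"`.
#' @param height_m Height in meters; `NA` yields `NA` pace.
#' @param step_length_k Named multipliers of height giving step length.
#' @return Pace in meters/second.
#' @export
#' @examples
#' peak30_pace(2, "male", 1.70)  # 2 * 0.415 * 1.70 = 1.411 m/s
peak30_pace <- function(cadence, gender = "unspecified", height_m = NA_real_,
                        step_length_k = .WW_STEP_LENGTH_K) {
  gender <- as.character(gender)
  gender[is.na(gender) | !gender %in% names(step_length_k)] <- "unspecified"
  cadence * step_length_k[gender] * height_m
}

#' Empirical bout-duration percentile
#'
#' 95th-percentile bout duration ("highest bout duration below the top 5%
#' longest bouts"), computed as an empirical quantile with linear
#' interpolation by default; the interpolation rule is configurable via
#' `type` (see [stats::quantile()]).
#'
#' @param durations Numeric bout durations in seconds.
#' @param prob Quantile level (default 0.95).
#' @param type Quantile algorithm (default 7, linear interpolation).
#' @return The quantile, or `NA` for zero bouts.
#' @export
bout_duration_p95 <- function(durations, prob = 0.95, type = 7) {
  if (length(durations) == 0L) return(NA_real_)
  unname(stats::quantile(durations, probs = prob, type = type, names = FALSE))
}

#' Daily walking measures for one participant-day-device
#'
#' @param day_epochs Epoch data.table (columns `epoch_start`, `steps`,
#'   `worn`) for a single participant-day-device, time-sorted.
#' @param gender,height_m Participant metadata for the pace conversion;
#'   missing height yields `NA` pace.
#' @param walk_threshold,max_gap,min_duration Bout-detection parameters,
#'   see [detect_bouts()].
#' @param short_max,long_min Bout-class boundaries in seconds: short bouts
#'   span `[min_duration, short_max)`, long bouts `>= long_min`; bouts in
#'   between count only toward the total.
#' @param grid_seconds Epoch grid in seconds.
#' @return One-row `data.table`: `step_count`, `n_bouts`, `n_short_bouts`,
#'   `n_long_bouts`, `bout_duration_mean/sd/p95` (seconds; `NA` when
#'   undefined: all bout statistics on zero-bout days, the SD on
#'   single-bout days), `peak30_cadence` (steps/s), `peak30_pace` (m/s),
#'   `ambulatory_time` (hours in qualifying epochs) and `wear_time`
#'   (hours).
#' @export
daily_measures <- function(day_epochs, gender = "unspecified",
                           height_m = NA_real_, walk_threshold = 6L,
                           max_gap = 20, min_duration = 30,
                           short_max = 60, long_min = 120,
                           grid_seconds = 10L) {
  steps <- day_epochs$steps
  bouts <- detect_bouts(day_epochs$epoch_start, steps,
                        walk_threshold = walk_threshold, max_gap = max_gap,
                        min_duration = min_duration,
                        grid_seconds = grid_seconds)
  nb <- nrow(bouts)
  dur <- bouts$duration
  cad <- peak30_cadence(steps, grid_seconds = grid_seconds)
  data.table::data.table(
    step_count = sum(steps),
    n_bouts = nb,
    n_short_bouts = sum(dur < short_max),
    n_long_bouts = sum(dur >= long_min),
    bout_duration_mean = if (nb > 0L) mean(dur) else NA_real_,
    bout_duration_sd = if (nb > 1L) stats::sd(dur) else NA_real_,
    bout_duration_p95 = bout_duration_p95(dur),
    peak30_cadence = cad,
    peak30_pace = unname(peak30_pace(cad, gender, height_m)),
    ambulatory_time = sum(steps >= walk_threshold) * grid_seconds / 3600,
    wear_time = sum(day_epochs$worn) * grid_seconds / 3600
  )
}

#' Compute daily measures for every participant-day-device in a cohort
#'
#' Splits an epoch table by participant, device and calendar day (local
#' midnight of `tz`; an epoch belongs to the day containing its start) and
#' applies [daily_measures()] to each group.
#'
#' @param epochs Epoch data.table as returned by [read_epochs()] or
#'   [simulate_cohort()].
#' @param meta Optional participant metadata ([read_participant_meta()]);
#'   when absent, pace is `NA`.
#' @param tz Timezone defining calendar-day boundaries (default `"UTC"`).
#' @param ... Passed to [daily_measures()].
#' @return `data.table` with one row per participant-day-device:
#'   `participant_id`, `device`, `date`, and the [daily_measures()]
#'   columns.
#' @export
compute_daily_measures <- function(epochs, meta = NULL, tz = "UTC", ...) {
  dt <- data.table::copy(data.table::as.data.table(epochs))
  dt[, date := as.Date(epoch_start, tz = tz)]
  data.table::setorder(dt, participant_id, device, epoch_start)
  if (!is.null(meta)) {
    meta <- data.table::as.data.table(meta)
    dt <- meta[, .(participant_id, gender, height_m)][dt, on = "participant_id"]
    dt[is.na(gender), gender := "unspecified"]
  } else {
    dt[, `:=`(gender = "unspecified", height_m = NA_real_)]
  }
  out <- dt[, daily_measures(.SD, gender = as.character(gender[1L]),
                             height_m = height_m[1L], ...),
            by = .(participant_id, device, date),
            .SDcols = c("epoch_start", "steps", "worn", "gender", "height_m")]
  data.table::setkey(out, participant_id, device, date)
  out[]
}

#' Filter participant-days for the accuracy analysis
#'
#' Retains a participant-day only when both devices have a record for that
#' day (the devices were worn simultaneously) and each device's record
#' shows at least `min_wear` hours of wear and strictly more than
#' `min_steps` steps.
#'
#' @param daily Daily-measures table from [compute_daily_measures()]
#'   containing both devices.
#' @param min_wear Minimum wear time in hours (default 8).
#' @param min_steps Step count must strictly exceed this (default 100).
#' @return The retained rows of `daily` (both devices).
#' @export
filter_accuracy_days <- function(daily, min_wear = 8, min_steps = 100) {
  dt <- data.table::as.data.table(daily)
  ok <- dt[, .(keep = .N == 2L && all(wear_time >= min_wear) &&
                 all(step_count > min_steps)),
           by = .(participant_id, date)]
  dt[ok[keep == TRUE], on = c("participant_id", "date")][, -"keep"][]
}

#' Write / read a daily-measures table as CSV
#'
#' Nulls (undefined bout statistics) are written as empty cells.
#'
#' @param daily Daily-measures data.table.
#' @param path CSV path.
#' @return `path` invisibly (`write_daily_measures`) or the table
#'   (`read_daily_measures`).
#' @export
write_daily_measures <- function(daily, path) {
  data.table::fwrite(daily, path, na = "")
  invisible(path)
}

#' @rdname write_daily_measures
#' @export
read_daily_measures <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "participant_id"))
  dt[, date := as.Date(date)]
  if ("device" %in% names(dt))
    dt[, device := factor(as.character(device), levels = .WW_DEVICES)]
  data.table::setkeyv(dt, intersect(c("participant_id", "device", "date"), names(dt)))
  dt[]
}
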