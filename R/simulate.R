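## Synthetic cohort generator.
##
## Emulates multi-day, multi-participant cohorts of 10-second-epoch step
## counts with (i) a per-participant latent activity level (between-subject
## variance), (ii) day-to-day variation injected through the bout-process
## intensity (within-subject variance), (iii) bout-structured walking with
## log-normal bout durations and Gaussian walking cadence, (iv) sparse
## sub-threshold incidental stepping, (v) contiguous daytime wear blocks
## with randomized edges, and (vi) correlated two-device readouts: both
## devices observe the same latent stream, the reference with small
## additive epoch noise, the study device with larger noise plus missed
## epochs.
##
## The bout process is built to realize each day's step target closely
## (bouts are accumulated until the target is met), so the daily step
## total carries the configured (between, within) variance decomposition
## up to a granularity of a few steps.  When an exact decomposition on
## large cohorts is required cheaply (reliability parameter recovery,
## coverage studies), the day-level generators simulate_daily_cohort() /
## simulate_paired_days() realize the components directly on daily totals
## without materializing epochs.

#' Configuration for the epoch-level cohort simulator
#'
#' Defaults describe a healthy adult cohort: ~10,000 steps/day with
#' between-subject SD 1800 and day-to-day within-subject SD 3900 steps
#' (jointly matching an overall daily-step SD of ~4300 and a two-week-scale
#' time to reliability), ~14 h daytime wear, 1.7 steps/s walking cadence,
#' and a study device noisier than the reference.
#'
#' @param n_participants,n_days Cohort size and days per participant.
#' @param seed Integer seed; identical (seed, config) give bit-identical
#'   cohorts.
#' @param mean_daily_steps Cohort mean daily step count.
#' @param between_subject_sd,within_subject_sd SDs (steps/day) of the
#'   participant level and the day level.
#' @param bout_duration_log_mean,bout_duration_log_sd Log-normal bout
#'   duration parameters (log-seconds).
#' @param cadence_mean,cadence_sd Walking-epoch cadence (steps/second);
#'   `cadence_mean` must not exceed the 6 steps/s cap.
#' @param wear_start,wear_end Nominal wear-block edges (hours of day).
#' @param wear_edge_sd SD (hours) of the day-to-day jitter of each edge.
#' @param incidental_rate Probability that a non-bout worn epoch carries
#'   incidental (sub-threshold, 1-5) steps.
#' @param reference_epoch_sd,study_epoch_sd Additive per-epoch noise SD
#'   (steps) for each device.
#' @param miss_prob Per-epoch probability that the study device misses the
#'   epoch entirely (records 0).
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 35L, n_days = 5L, seed = 1L,
                          mean_daily_steps = 10000,
                          between_subject_sd = 1800,
                          within_subject_sd = 3900,
                          bout_duration_log_mean = log(90),
                          bout_duration_log_sd = 0.8,
                          cadence_mean = 1.7, cadence_sd = 0.25,
                          wear_start = 7.5, wear_end = 21.5,
                          wear_edge_sd = 0.5,
                          incidental_rate = 0.05,
                          reference_epoch_sd = 0.5,
                          study_epoch_sd = 1.5,
                          miss_prob = 0.03) {
  cfg <- as.list(environment())
  stopifnot(n_participants >= 0, n_days >= 1,
            between_subject_sd >= 0, within_subject_sd >= 0,
            bout_duration_log_sd >= 0, cadence_sd >= 0,
            cadence_mean > 0, cadence_mean <= 6,
            incidental_rate >= 0, incidental_rate <= 1,
            miss_prob >= 0, miss_prob <= 1,
            reference_epoch_sd >= 0, study_epoch_sd >= 0,
            wear_start >= 0, wear_end <= 24, wear_end > wear_start)
  if (mean_daily_steps <= 0)
    stop("cohort_config(): mean_daily_steps must be positive")
  structure(cfg, class = "cohort_config")
}

#' Simulate an epoch-level two-device cohort
#'
#' @param config A [cohort_config()].
#' @return List with:
#'   \describe{
#'     \item{epochs}{epoch data.table for both devices (worn epochs only,
#'       `worn = TRUE`), valid under [validate_epochs()];}
#'     \item{meta}{participant metadata (balanced genders, heights ~
#'       N(1.70, 0.10) m clamped to a plausible range);}
#'     \item{truth}{list of `daily` (daily measures of the noiseless latent
#'       stream, computed with [daily_measures()]) and `participants`
#'       (latent activity level `b` per participant).}
#'   }
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(cfg$seed)
  P <- as.integer(cfg$n_participants)
  origin <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC")
  if (P == 0L) {
    empty <- data.table::data.table(
      participant_id = character(0),
      device = factor(character(0), levels = .WW_DEVICES),
      epoch_start = origin[0], steps = integer(0), worn = logical(0))
    meta <- data.table::data.table(
      participant_id = character(0),
      gender = factor(character(0), levels = c("female", "male", "unspecified")),
      height_m = numeric(0))
    return(list(epochs = empty, meta = meta,
                truth = list(daily = data.table::data.table(),
                             participants = data.table::data.table())))
  }
  ids <- sprintf("P%03d", seq_len(P))
  gender <- rep_len(c("female", "male"), P)
  height <- pmin(2.0, pmax(1.4, stats::rnorm(P, 1.70, 0.10)))
  meta <- data.table::data.table(
    participant_id = ids,
    gender = factor(gender, levels = c("female", "male", "unspecified")),
    height_m = round(height, 3))
  data.table::setkey(meta, participant_id)

  b <- stats::rnorm(P, 0, cfg$between_subject_sd)
  chunks <- vector("list", P * cfg$n_days)
  truth_rows <- vector("list", P * cfg$n_days)
  ci <- 0L
  for (i in seq_len(P)) {
    for (d in seq_len(cfg$n_days)) {
      ci <- ci + 1L
      day0 <- origin + (d - 1L) * 86400
      ## wear block with jittered edges, snapped to the grid
      ws <- max(0, cfg$wear_start + stats::rnorm(1, 0, cfg$wear_edge_sd))
      we <- min(24, cfg$wear_end + stats::rnorm(1, 0, cfg$wear_edge_sd))
      e0 <- as.integer(ceiling(ws * 360))   # index on the 10-s grid
      e1 <- as.integer(floor(we * 360))
      n_ep <- max(0L, e1 - e0)
      if (n_ep < 3L) next
      ## target daily steps from the variance components; the bout process
      ## below is built to realize the target closely, so the day-level
      ## variance decomposition is carried by (b_i, e_id), not by process
      ## noise
      target <- max(0, cfg$mean_daily_steps + b[i] +
                      stats::rnorm(1, 0, cfg$within_subject_sd))
      ## sparse sub-threshold incidental stepping on the base stream
      latent <- integer(n_ep)
      hit <- which(stats::runif(n_ep) < cfg$incidental_rate)
      latent[hit] <- sample(1:5, length(hit), replace = TRUE)
      ## accumulate bouts (log-normal durations, Gaussian cadence) until
      ## the step target is met or the wear block is mostly occupied
      bout_target <- target - sum(latent)
      bouts <- list()
      occ <- 0L; tot <- 0
      max_occ <- as.integer(floor(0.8 * n_ep))
      while (tot < bout_target && occ + 3L <= max_occ) {
        ne <- max(3L, as.integer(round(
          stats::rlnorm(1, cfg$bout_duration_log_mean,
                        cfg$bout_duration_log_sd) / 10)))
        ne <- min(ne, max_occ - occ)
        if (ne < 3L) break
        st <- pmin(60L, pmax(0L, as.integer(round(
          stats::rnorm(ne, 10 * cfg$cadence_mean, 10 * cfg$cadence_sd)))))
        cum <- cumsum(st)
        if (tot + cum[ne] > bout_target) {  # trim the overshooting tail
          keep <- max(3L, which(tot + cum >= bout_target)[1L])
          st <- st[seq_len(keep)]
          ne <- keep
        }
        bouts[[length(bouts) + 1L]] <- st
        occ <- occ + ne
        tot <- tot + sum(st)
      }
      nb <- length(bouts)
      if (nb > 0L) {
        ## scatter the bouts uniformly: compose the free epochs into nb+1 gaps
        lens <- lengths(bouts)
        gaps <- as.vector(stats::rmultinom(1L, n_ep - occ, rep(1, nb + 1L)))
        starts <- cumsum(gaps[seq_len(nb)]) +
          c(0L, cumsum(lens[-nb])) + 1L
        for (bj in seq_len(nb)) {
          idx <- starts[bj]:(starts[bj] + lens[bj] - 1L)
          latent[idx] <- bouts[[bj]]
        }
      }
      ## top up incidental steps for the small amount overwritten by bouts
      deficit <- round(target) - sum(latent)
      if (deficit > 0L) {
        free <- which(latent == 0L)
        if (length(free)) {
          fill <- sample(free, min(length(free), ceiling(deficit / 3)))
          add <- sample(1:5, length(fill), replace = TRUE)
          add <- add[cumsum(add) <= deficit + 4L]
          latent[fill[seq_along(add)]] <- add
        }
      }
      tstamps <- day0 + (e0 + seq_len(n_ep) - 1L) * 10
      ref <- pmin(60L, pmax(0L, latent + as.integer(round(
        stats::rnorm(n_ep, 0, cfg$reference_epoch_sd)))))
      stu <- pmin(60L, pmax(0L, latent + as.integer(round(
        stats::rnorm(n_ep, 0, cfg$study_epoch_sd)))))
      if (cfg$miss_prob > 0)
        stu[stats::runif(n_ep) < cfg$miss_prob] <- 0L
      chunks[[ci]] <- data.table::data.table(
        participant_id = ids[i],
        device = rep(c("study", "reference"), each = n_ep),
        epoch_start = c(tstamps, tstamps),
        steps = c(stu, ref),
        worn = TRUE)
      tm <- daily_measures(
        data.table::data.table(epoch_start = tstamps, steps = latent,
                               worn = TRUE),
        gender = gender[i], height_m = height[i])
      truth_rows[[ci]] <- data.table::data.table(
        participant_id = ids[i], date = as.Date(day0, tz = "UTC"), tm)
    }
  }
  epochs <- data.table::rbindlist(chunks)
  if (nrow(epochs)) {
    epochs[, device := factor(device, levels = .WW_DEVICES)]
    data.table::setkey(epochs, participant_id, device, epoch_start)
  }
  truth_daily <- data.table::rbindlist(truth_rows)
  list(epochs = epochs, meta = meta,
       truth = list(daily = truth_daily,
                    participants = data.table::data.table(
                      participant_id = ids, b = b)))
}

#' Day-level cohort with exact variance components
#'
#' Generates daily step counts directly as `mean + b_i + e_id`, with
#' `b_i ~ N(0, between_sd^2)` and `e_id ~ N(0, within_sd^2)`, and a
#' constant daily wear time.  Unlike [simulate_cohort()], the realized
#' between/within decomposition carries no extra process noise, which makes
#' this the right input for reliability parameter-recovery and coverage
#' studies against closed-form targets.
#'
#' @param n_participants,n_days Cohort dimensions.
#' @param mean_daily_steps Cohort mean.
#' @param between_sd,within_sd Variance-component SDs (steps/day).
#' @param wear_hours Constant daily wear time written to `wear_time`.
#' @param seed Integer seed.
#' @return data.table: `participant_id`, `date`, `wear_time`, `step_count`.
#' @export
simulate_daily_cohort <- function(n_participants, n_days,
                                  mean_daily_steps = 10000,
                                  between_sd = 1800, within_sd = 3900,
                                  wear_hours = 14, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  ids <- sprintf("P%03d", seq_len(n_participants))
  b <- stats::rnorm(n_participants, 0, between_sd)
  dt <- data.table::CJ(participant_id = ids,
                       date = as.Date("2024-03-01") + 0:(n_days - 1L))
  dt[, `:=`(wear_time = wear_hours,
            step_count = mean_daily_steps + b[match(participant_id, ids)] +
              stats::rnorm(.N, 0, within_sd))]
  data.table::setattr(dt, "b", stats::setNames(b, ids))
  dt[]
}

#' Paired day-level readouts with a known device bias
#'
#' Reference readouts follow the day-level cohort model; study readouts add
#' a constant bias, a participant-level device offset (which induces the
#' within-participant error correlation that makes participant-clustered
#' CIs necessary), and i.i.d. day-level device noise.  The true mean error
#' (study - reference) is exactly `bias`.
#'
#' @inheritParams simulate_daily_cohort
#' @param bias Constant study-device offset (steps/day).
#' @param device_sd SD of the study-device day-level noise.
#' @param device_between_sd SD of the per-participant study-device offset.
#' @return data.table: `participant_id`, `date`, `study`, `reference`.
#' @export
simulate_paired_days <- function(n_participants, n_days, bias = 0,
                                 device_sd = 500, device_between_sd = 300,
                                 mean_daily_steps = 10000,
                                 between_sd = 1800, within_sd = 3900,
                                 seed = 1L) {
  dt <- simulate_daily_cohort(n_participants, n_days,
                              mean_daily_steps = mean_daily_steps,
                              between_sd = between_sd,
                              within_sd = within_sd, seed = seed)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed + 1L)
  ids <- unique(dt$participant_id)
  gam <- stats::setNames(stats::rnorm(length(ids), 0, device_between_sd), ids)
  dt[, .(participant_id, date, reference = step_count,
         study = step_count + bias + gam[participant_id] +
           stats::rnorm(.N, 0, device_sd))]
}

#' Hand-checkable worked fixtures
#'
#' Deterministic miniature epoch tables exercising the documented edge
#' cases of the pipeline.
#'
#' @return Named list of epoch data.tables:
#'   \describe{
#'     \item{minimal_bout}{three qualifying epochs -> exactly one 30-s
#'       bout;}
#'     \item{bridged_gap}{steps 8,0,0,9,7,8 -> one 60-s bout with 4
#'       qualifying epochs (20-s gap bridged);}
#'     \item{split_gap}{steps 8,0,0,0,9,7,8 -> the 30-s gap splits; only
#'       the 3-epoch tail survives as a 30-s bout;}
#'     \item{low_wear_day}{two-device day with 7.9 h wear on the study
#'       device -> dropped by [filter_accuracy_days()];}
#'     \item{exact_100_steps}{two-device day with >= 8 h wear and exactly
#'       100 steps on each device -> dropped by the strict > 100 rule;}
#'     \item{reliability_toy}{one participant, four high-wear days with
#'       known daily step counts, for window-mean checks.}
#'   }
#' @export
make_worked_fixtures <- function() {
  t0 <- as.POSIXct("2024-05-01 09:00:00", tz = "UTC")
  ep <- function(steps, start = t0, id = "p1", device = "study") {
    n <- length(steps)
    data.table::data.table(
      participant_id = id,
      device = factor(device, levels = .WW_DEVICES),
      epoch_start = start + seq(0, by = 10, length.out = n),
      steps = as.integer(steps),
      worn = TRUE)
  }
  day0 <- as.POSIXct("2024-05-01 08:00:00", tz = "UTC")
  ## 7.9 h = 2844 worn epochs on the study device, 8 h on the reference;
  ## plenty of steps so only the wear filter bites
  low_wear <- data.table::rbindlist(list(
    ep(rep(c(8L, rep(0L, 9L)), length.out = 2844L), start = day0),
    ep(rep(c(8L, rep(0L, 9L)), length.out = 2880L), start = day0,
       device = "reference")))
  ## >= 8 h wear but exactly 100 steps (20 epochs x 5 sub-threshold steps)
  exact100 <- data.table::rbindlist(list(
    ep(rep(c(5L, rep(0L, 143L)), length.out = 2880L), start = day0),
    ep(rep(c(5L, rep(0L, 143L)), length.out = 2880L), start = day0,
       device = "reference")))
  stopifnot(sum(exact100$steps) == 200L)
  toy_days <- as.POSIXct(c("2024-05-01", "2024-05-02", "2024-05-03",
                           "2024-05-04"), tz = "UTC") + 9 * 3600
  toy <- data.table::rbindlist(lapply(seq_along(toy_days), function(d) {
    ## 4680 epochs = 13 h wear; 8-step epochs spread to avoid bouts
    n_active <- c(800L, 900L, 1000L, 1100L)[d]
    steps <- rep(0L, 4680L)
    steps[seq_len(n_active) * 4L] <- 8L
    ep(steps, start = toy_days[d])
  }))
  list(
    minimal_bout = ep(c(8L, 9L, 7L)),
    bridged_gap = ep(c(8L, 0L, 0L, 9L, 7L, 8L)),
    split_gap = ep(c(8L, 0L, 0L, 0L, 9L, 7L, 8L)),
    low_wear_day = low_wear,
    exact_100_steps = exact100,
    reliability_toy = toy
  )
}
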