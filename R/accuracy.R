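## Two-device accuracy characterization.
##
## All metrics are computed on retained participant-days (see
## filter_accuracy_days()) with study and reference readouts paired by
## participant-day.  Confidence intervals resample participants (clusters)
## with replacement, carrying all of a participant's days, to respect the
## repeated-measures structure (typically ~5 days per participant).

#' Point agreement metrics for one measure
#'
#' @param study,reference Paired numeric readouts (study device, reference
#'   device) for the same participant-days.  Pairs with a missing value in
#'   either member are dropped (pairwise deletion, so zero-bout days with
#'   undefined bout statistics do not remove the day from other measures).
#' @return Named list: `icc` (Fisher ICC), `pearson_r`, `pearson_p`
#'   (two-sided, treating participant-days as independent), `me` (mean
#'   error, study - reference), `mae` (mean absolute error), `n` (pairs
#'   used).  All statistics are `NA` with fewer than 2 valid pairs.
#' @export
accuracy_metrics <- function(study, reference) {
  stopifnot(length(study) == length(reference))
  ok <- is.finite(study) & is.finite(reference)
  x <- study[ok]; y <- reference[ok]
  n <- length(x)
  if (n < 2L)
    return(list(icc = NA_real_, pearson_r = NA_real_, pearson_p = NA_real_,
                me = NA_real_, mae = NA_real_, n = n))
  d <- x - y
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    NA_real_
  } else if (all(d == d[1])) {
    1  # y = x + c: exactly correlated, avoid sqrt round-off
  } else {
    stats::cor(x, y)
  }
  p <- if (is.na(r) || n < 3L || abs(r) >= 1) {
    if (identical(abs(r), 1)) 0 else NA_real_
  } else {
    tv <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tv), df = n - 2)
  }
  list(icc = suppressWarnings(fisher_icc(x, y)), pearson_r = r, pearson_p = p,
       me = mean(d), mae = mean(abs(d)), n = n)
}

#' Bland-Altman agreement summary
#'
#' Bias and 95% limits of agreement of the between-device differences, plus
#' the point set for a modified Bland-Altman plot in which the x-coordinate
#' is the reference-device value (rather than the pair mean) because the
#' reference carries the low-error truth labels.
#'
#' @inheritParams accuracy_metrics
#' @param loa_z Normal multiplier for the limits of agreement (default
#'   1.96).
#' @return List with `bias`, `loa_low`, `loa_high` (`bias +/- loa_z *
#'   SD(differences)`) and `points`, a data.table of
#'   `(reference_value, difference)`.
#' @export
bland_altman <- function(study, reference, loa_z = 1.96) {
  ok <- is.finite(study) & is.finite(reference)
  x <- study[ok]; y <- reference[ok]
  if (length(x) < 2L)
    return(list(bias = NA_real_, loa_low = NA_real_, loa_high = NA_real_,
                points = data.table::data.table(reference_value = y,
                                                difference = x - y)))
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - loa_z * s, loa_high = bias + loa_z * s,
       points = data.table::data.table(reference_value = y, difference = d))
}

#' Participant-clustered percentile bootstrap confidence interval
#'
#' Resamples participants (clusters) with replacement, carrying all of each
#' resampled participant's rows, and returns the percentile interval of the
#' statistic across replicates.  Replicates on which the statistic is
#' undefined (e.g. zero-variance resamples for a correlation) are redrawn,
#' up to a capped number of retries.
#'
#' @param data A data.frame/data.table of rows to resample.
#' @param cluster Name of the cluster (participant) id column.
#' @param statistic `function(data_subset) -> scalar`.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed; for a fixed seed the interval is
#'   deterministic.
#' @param max_redraws Cap on total redraws of degenerate replicates.
#' @return `c(low, high)`; `NA`s if too few clusters or all replicates
#'   degenerate.
#' @export
cluster_bootstrap_ci <- function(data, cluster = "participant_id", statistic,
                                 n_boot = 1000L, level = 0.95, seed = NULL,
                                 max_redraws = 10L * n_boot) {
  dt <- data.table::as.data.table(data)
  ids <- unique(dt[[cluster]])
  k <- length(ids)
  if (k < 2L) return(c(NA_real_, NA_real_))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  rows_by_id <- split(seq_len(nrow(dt)), factor(dt[[cluster]], levels = ids))
  stats_out <- rep(NA_real_, n_boot)
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      pick <- sample.int(k, k, replace = TRUE)
      rows <- unlist(rows_by_id[pick], use.names = FALSE)
      val <- suppressWarnings(statistic(dt[rows]))
      if (is.finite(val)) break
      redraws <- redraws + 1L
      if (redraws > max_redraws) {
        warning("cluster_bootstrap_ci(): redraw cap reached; interval undefined")
        return(c(NA_real_, NA_real_))
      }
    }
    stats_out[b] <- val
  }
  alpha <- (1 - level) / 2
  unname(stats::quantile(stats_out, c(alpha, 1 - alpha), names = FALSE))
}

#' Full agreement report across all daily walking measures
#'
#' Applies [accuracy_metrics()], [bland_altman()] and participant-clustered
#' bootstrap CIs to every measure of a paired daily table.
#'
#' @param daily Daily-measures table containing both devices, already
#'   filtered with [filter_accuracy_days()] (or not, at the caller's
#'   choice).
#' @param measures Character vector of measure columns (default all nine
#'   [walking_measures()]).
#' @param n_boot Bootstrap replicates per metric (default 1000).
#' @param level CI level (default 0.95).
#' @param seed Integer seed making the whole report reproducible.
#' @return List with `metrics`: a data.table with one row per measure
#'   (`icc`, `icc_low/high`, `pearson_r`, `pearson_low/high`, `pearson_p`,
#'   `me`, `me_low/high`, `mae`, `mae_low/high`, `ba_bias`, `ba_loa_low`,
#'   `ba_loa_high`, `n_participant_days`, `n_participants`), and
#'   `bland_altman`: named list of per-measure point sets.
#' @export
agreement_report <- function(daily, measures = walking_measures(),
                             n_boot = 1000L, level = 0.95, seed = 1L) {
  dt <- data.table::as.data.table(daily)
  wide <- data.table::dcast(
    dt, participant_id + date ~ device, value.var = measures)
  rows <- vector("list", length(measures))
  ba_points <- stats::setNames(vector("list", length(measures)), measures)
  for (i in seq_along(measures)) {
    m <- measures[i]
    scol <- if (length(measures) > 1L) paste0(m, "_study") else "study"
    rcol <- if (length(measures) > 1L) paste0(m, "_reference") else "reference"
    sub <- wide[is.finite(wide[[scol]]) & is.finite(wide[[rcol]]),
                c("participant_id", "date", scol, rcol), with = FALSE]
    data.table::setnames(sub, c(scol, rcol), c("study", "reference"))
    pt <- accuracy_metrics(sub$study, sub$reference)
    ba <- bland_altman(sub$study, sub$reference)
    ba_points[[m]] <- ba$points
    ci <- function(stat_fun, s) cluster_bootstrap_ci(
      sub, "participant_id", stat_fun, n_boot = n_boot, level = level,
      seed = seed + s)
    icc_ci <- ci(function(d) fisher_icc(d$study, d$reference), 1000L * i + 1L)
    r_ci <- ci(function(d) accuracy_metrics(d$study, d$reference)$pearson_r,
               1000L * i + 2L)
    me_ci <- ci(function(d) mean(d$study - d$reference), 1000L * i + 3L)
    mae_ci <- ci(function(d) mean(abs(d$study - d$reference)), 1000L * i + 4L)
    rows[[i]] <- data.table::data.table(
      measure = m, icc = pt$icc, icc_low = icc_ci[1], icc_high = icc_ci[2],
      pearson_r = pt$pearson_r, pearson_low = r_ci[1], pearson_high = r_ci[2],
      pearson_p = pt$pearson_p,
      me = pt$me, me_low = me_ci[1], me_high = me_ci[2],
      mae = pt$mae, mae_low = mae_ci[1], mae_high = mae_ci[2],
      ba_bias = ba$bias, ba_loa_low = ba$loa_low, ba_loa_high = ba$loa_high,
      n_participant_days = pt$n,
      n_participants = data.table::uniqueN(sub$participant_id))
  }
  list(metrics = data.table::rbindlist(rows), bland_altman = ba_points)
}
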