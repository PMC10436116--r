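## Time-to-reliability: test-retest ICC between adjacent non-overlapping
## windows of rolling-mean daily measures, across aggregation scopes of
## 1..max_scope days.
##
## For a scope of k days, windows are [start, start+k) and [start+k,
## start+2k) in each participant's own day index (day 0 = first observed
## day).  A window is valid for a participant when at least
## ceiling(min_wear_fraction * k) of its days have >= min_daily_wear hours
## of wear; window means are taken over those valid days (days below the
## wear bar are excluded from the mean).  Per start offset, one
## (window-A mean, window-B mean) pair per eligible participant enters a
## Fisher ICC across participants; the scope's ICC is the mean of
## per-offset ICCs over all offsets with >= 2 eligible participants.
## Confidence intervals bootstrap participants (clusters) through the whole
## procedure.

#' Internal: per-participant day-indexed arrays for one measure
#'
#' @noRd
.reliability_arrays <- function(daily, measure, min_daily_wear) {
  dt <- data.table::as.data.table(daily)
  if ("device" %in% names(dt)) {
    ndev <- data.table::uniqueN(stats::na.omit(as.character(dt$device)))
    if (ndev > 1L)
      stop("reliability input must contain a single device; subset first")
  }
  dt <- dt[, .(participant_id, date, wear_time,
               value = as.numeric(dt[[measure]]))]
  dt[, day_index := as.integer(date - min(date)), by = participant_id]
  ids <- sort(unique(dt$participant_id))
  P <- length(ids)
  D <- max(dt$day_index) + 1L
  V <- matrix(FALSE, P, D)  # day passes the wear bar
  X <- matrix(0, P, D)      # measure value on usable days, else 0
  M <- matrix(FALSE, P, D)  # usable: passes wear bar and measure non-null
  pi <- match(dt$participant_id, ids)
  idx <- cbind(pi, dt$day_index + 1L)
  vv <- dt$wear_time >= min_daily_wear
  V[idx] <- vv
  mm <- vv & is.finite(dt$value)
  M[idx] <- mm
  X[idx[mm, , drop = FALSE]] <- dt$value[mm]
  list(ids = ids, V = V, X = X, M = M, n_days = D)
}

#' Internal: row-wise window sums over all start offsets for scope k
#'
#' Returns a P x O matrix whose (i, o) entry is the sum of `mat[i, o..o+k-1]`.
#' @noRd
.window_sums <- function(mat, k) {
  cs <- cbind(0, t(apply(mat, 1L, cumsum)))
  O <- ncol(mat) - k + 1L
  cs[, (k + 1L):(k + O), drop = FALSE] - cs[, 1L:O, drop = FALSE]
}

#' Internal: adjacent-window pair means and eligibility for one scope
#'
#' @return list of P x O matrices `A`, `B` (window means, 0 where not
#'   eligible) and logical `E` (participant eligible at offset), with O the
#'   number of start offsets.
#' @noRd
.window_pairs <- function(arr, k, min_wear_fraction) {
  D <- arr$n_days
  if (D < 2L * k) return(NULL)
  O <- D - 2L * k + 1L
  need <- ceiling(min_wear_fraction * k)
  vA <- .window_sums(arr$V + 0, k); vB <- vA[, (k + 1L):(k + O), drop = FALSE]
  vA <- vA[, 1L:O, drop = FALSE]
  mA <- .window_sums(arr$M + 0, k); mB <- mA[, (k + 1L):(k + O), drop = FALSE]
  mA <- mA[, 1L:O, drop = FALSE]
  sA <- .window_sums(arr$X, k); sB <- sA[, (k + 1L):(k + O), drop = FALSE]
  sA <- sA[, 1L:O, drop = FALSE]
  E <- vA >= need & vB >= need & mA >= 1 & mB >= 1
  A <- matrix(0, nrow(E), ncol(E)); B <- A
  A[E] <- sA[E] / mA[E]
  B[E] <- sB[E] / mB[E]
  list(A = A, B = B, E = E)
}

#' Internal: per-offset weighted Fisher ICCs, averaged over valid offsets
#'
#' `w` is a participant multiplicity vector (bootstrap resample counts);
#' offsets need >= 2 distinct participants and nonzero pooled variance.
#' @noRd
.offset_mean_icc <- function(wp, w) {
  E <- wp$E; A <- wp$A; B <- wp$B
  W <- E * w                         # recycled down columns
  n <- colSums(W)
  npart <- colSums(E & w > 0)
  Sx <- colSums(W * A); Sy <- colSums(W * B)
  Sx2 <- colSums(W * A * A); Sy2 <- colSums(W * B * B)
  Sxy <- colSums(W * A * B)
  m <- (Sx + Sy) / (2 * n)
  num <- Sxy - m * (Sx + Sy) + n * m^2
  ss <- Sx2 + Sy2 - 2 * m * (Sx + Sy) + 2 * n * m^2
  ok <- npart >= 2 & is.finite(ss) & ss > .Machine$double.eps * pmax(1, n)
  if (!any(ok)) return(NA_real_)
  mean(2 * num[ok] / ss[ok])
}

#' Participants eligible at an aggregation scope
#'
#' A participant is eligible at scope `k` when they have at least one start
#' offset at which both adjacent k-day windows contain at least
#' `ceiling(min_wear_fraction * k)` days with `>= min_daily_wear` hours of
#' wear (so the observation span must be at least `2k` days).
#'
#' @param daily Single-device daily-measures table (needs `participant_id`,
#'   `date`, `wear_time`).
#' @param k Aggregation scope in days.
#' @param min_daily_wear Daily wear bar in hours (default 12).
#' @param min_wear_fraction Minimum fraction of valid days per window
#'   (default 0.5).
#' @return data.table of eligible participants with their valid start
#'   offsets (`participant_id`, `start_offset`, 0-based relative to the
#'   participant's first observed day).
#' @export
eligible_participants <- function(daily, k, min_daily_wear = 12,
                                  min_wear_fraction = 0.5) {
  dt <- data.table::as.data.table(daily)
  arr <- .reliability_arrays(
    dt[, .(participant_id, date, wear_time, dummy = 1)], "dummy",
    min_daily_wear)
  wp <- .window_pairs(arr, k, min_wear_fraction)
  if (is.null(wp))
    return(data.table::data.table(participant_id = character(0),
                                  start_offset = integer(0)))
  idx <- which(wp$E, arr.ind = TRUE)
  out <- data.table::data.table(participant_id = arr$ids[idx[, 1L]],
                                start_offset = idx[, 2L] - 1L)
  data.table::setorder(out, participant_id, start_offset)
  out[]
}

#' Adjacent-window means for one participant, scope and offset
#'
#' @param daily Single-device daily table.
#' @param participant Participant id.
#' @param k Scope in days.
#' @param start_offset 0-based offset from the participant's first observed
#'   day; windows are `[o, o+k)` and `[o+k, o+2k)`.
#' @param measure Measure column name.
#' @inheritParams eligible_participants
#' @return `c(mean_a, mean_b)`: within-window means over days meeting the
#'   wear bar (and with a non-null measure value); `NA` for a window with
#'   no usable day.
#' @export
window_means <- function(daily, participant, k, start_offset, measure,
                         min_daily_wear = 12) {
  dt <- data.table::as.data.table(daily)[participant_id == participant]
  if (nrow(dt) == 0L) return(c(mean_a = NA_real_, mean_b = NA_real_))
  dt[, day_index := as.integer(date - min(date))]
  win_mean <- function(lo, hi) {
    v <- as.numeric(dt[day_index >= lo & day_index < hi &
                         wear_time >= min_daily_wear][[measure]])
    v <- v[is.finite(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  c(mean_a = win_mean(start_offset, start_offset + k),
    mean_b = win_mean(start_offset + k, start_offset + 2L * k))
}

#' Adjacent-window ICC at one aggregation scope
#'
#' @inheritParams eligible_participants
#' @param measure Measure column name.
#' @param n_boot Participant-clustered bootstrap replicates for the CI
#'   (default 200; 0 skips the CI).
#' @param level CI level.
#' @param seed Integer seed for the bootstrap.
#' @return List: `icc` (mean of per-offset Fisher ICCs over offsets with
#'   >= 2 eligible participants; `NA` when no such offset), `ci_low`,
#'   `ci_high`, `n_participants` (eligible at >= 1 offset), `n_offsets`.
#' @export
adjacent_window_icc <- function(daily, k, measure, min_daily_wear = 12,
                                min_wear_fraction = 0.5, n_boot = 200L,
                                level = 0.95, seed = 1L) {
  arr <- .reliability_arrays(daily, measure, min_daily_wear)
  wp <- .window_pairs(arr, k, min_wear_fraction)
  P <- length(arr$ids)
  empty <- list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n_participants = 0L, n_offsets = 0L)
  if (is.null(wp)) return(empty)
  n_off <- sum(colSums(wp$E) >= 2L)
  if (n_off == 0L) return(empty)
  point <- .offset_mean_icc(wp, rep(1, P))
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L && P >= 2L) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    reps <- rep(NA_real_, n_boot)
    tries <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        w <- tabulate(sample.int(P, P, replace = TRUE), nbins = P)
        val <- .offset_mean_icc(wp, w)
        if (is.finite(val)) break
        tries <- tries + 1L
        if (tries > 10L * n_boot) { val <- NA_real_; break }
      }
      reps[b] <- val
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    alpha <- (1 - level) / 2
    if (all(is.finite(reps)))
      ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE))
  }
  list(icc = point, ci_low = ci[1], ci_high = ci[2],
       n_participants = sum(rowSums(wp$E) > 0L), n_offsets = n_off)
}

#' Reliability curve across aggregation scopes
#'
#' Computes the adjacent-window ICC (with CI and cohort size) for each
#' measure and each scope, and the resulting time to reliability.
#'
#' @inheritParams adjacent_window_icc
#' @param measures Measure columns; by default all daily walking measures
#'   except peak 30-minute pace, which is a deterministic rescaling of peak
#'   30-minute cadence and would duplicate its curve.
#' @param scopes Integer aggregation scopes in days (default `1:30`).
#' @param threshold Reliability threshold on the ICC (default 0.75).
#' @return data.table with one row per measure x scope: `measure`, `scope`,
#'   `icc`, `ci_low`, `ci_high`, `n_participants`, `n_offsets`, plus an
#'   attribute `time_to_reliability`: a data.table of `measure`,
#'   `time_to_reliability` (days, `NA` when the threshold is never
#'   reached).
#' @export
reliability_curve <- function(daily,
                              measures = setdiff(walking_measures(),
                                                 "peak30_pace"),
                              scopes = 1:30, threshold = 0.75,
                              min_daily_wear = 12, min_wear_fraction = 0.5,
                              n_boot = 200L, level = 0.95, seed = 1L) {
  measures <- intersect(measures, names(daily))
  rows <- list()
  for (m in measures) {
    for (k in sort(unique(as.integer(scopes)))) {
      res <- adjacent_window_icc(daily, k, m,
                                 min_daily_wear = min_daily_wear,
                                 min_wear_fraction = min_wear_fraction,
                                 n_boot = n_boot, level = level,
                                 seed = seed + 131L * k)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        measure = m, scope = k, icc = res$icc, ci_low = res$ci_low,
        ci_high = res$ci_high, n_participants = res$n_participants,
        n_offsets = res$n_offsets)
    }
  }
  out <- data.table::rbindlist(rows)
  ttr <- out[, .(time_to_reliability =
                   time_to_reliability(icc, scope, threshold = threshold)),
             by = measure]
  data.table::setattr(out, "time_to_reliability", ttr)
  out[]
}

#' Time to reliability from an ICC-by-scope curve
#'
#' The smallest aggregation scope whose ICC meets the reliability
#' threshold.
#'
#' @param icc Numeric ICC values.
#' @param scope Integer scopes (days) matching `icc`; defaults to
#'   `seq_along(icc)`.
#' @param threshold Reliability threshold (default 0.75).
#' @return The smallest scope with `icc >= threshold`, or `NA_integer_`
#'   when the curve never reaches it.
#' @export
#' @examples
#' time_to_reliability(c(0.5, 0.7, 0.76, 0.8))  # 3
time_to_reliability <- function(icc, scope = seq_along(icc),
                                threshold = 0.75) {
  stopifnot(length(icc) == length(scope))
  o <- order(scope)
  icc <- icc[o]; scope <- as.integer(scope[o])
  hit <- which(!is.na(icc) & icc >= threshold)
  if (length(hit) == 0L) NA_integer_ else scope[hit[1L]]
}
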