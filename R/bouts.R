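## Walking-bout detection on the 10-second epoch grid.
##
## A walking bout is a maximal series of qualifying epochs (>= 6 steps
## each) in which consecutive qualifying epochs are separated by at most
## 20 s of non-qualifying time (i.e. at most two empty epochs), containing
## at least 3 qualifying epochs and spanning at least 30 s.  The bout
## duration is the span from the start of the first qualifying epoch to
## the end of the last one, so bridged gap epochs count toward duration.

#' Detect walking bouts in one day of epoch step counts
#'
#' @param epoch_start POSIXct (or numeric seconds) epoch-start times on the
#'   grid, strictly increasing; missing epochs are treated as
#'   non-qualifying time.
#' @param steps Integer step counts, same length as `epoch_start`.
#' @param walk_threshold Minimum steps for an epoch to qualify as walking
#'   (default 6).
#' @param max_gap Maximum non-qualifying interruption, in seconds, bridged
#'   within a bout (default 20, i.e. two empty epochs).
#' @param min_duration Minimum bout span in seconds (default 30).
#' @param grid_seconds Epoch grid in seconds (default 10).
#' @return A `data.table` of disjoint, time-ordered bouts with columns
#'   `start`, `end` (end-exclusive), `n_walk_epochs`, and `duration`
#'   (`end - start`, seconds, including bridged gaps).  Zero rows when no
#'   bout qualifies.
#' @details A bout must contain at least `ceiling(min_duration /
#'   grid_seconds)` qualifying epochs *and* span at least `min_duration`
#'   seconds; a two-epoch run stretched past 30 s by a bridged gap is
#'   therefore still rejected.
#' @export
#' @examples
#' t0 <- as.POSIXct("2024-05-01 09:00:00", tz = "UTC")
#' detect_bouts(t0 + seq(0, 50, by = 10), c(8, 0, 0, 9, 7, 8))  # one 60-s bout
detect_bouts <- function(epoch_start, steps, walk_threshold = 6L,
                         max_gap = 20, min_duration = 30,
                         grid_seconds = 10L) {
  stopifnot(length(epoch_start) == length(steps))
  t <- as.numeric(epoch_start)
  if (is.unsorted(t, strictly = TRUE))
    stop("epochs must be strictly increasing in time")
  if (any(t %% grid_seconds != 0))
    stop("epoch_start values must lie on the ", grid_seconds, "-second grid")
  min_epochs <- as.integer(ceiling(min_duration / grid_seconds))

  q <- which(steps >= walk_threshold)
  if (length(q) == 0L) return(.empty_bouts(epoch_start))
  tq <- t[q]
  ## break the chain when the wall-clock interruption between the end of
  ## one qualifying epoch and the start of the next exceeds max_gap
  new_run <- c(TRUE, diff(tq) - grid_seconds > max_gap)
  run_id <- cumsum(new_run)
  first <- tq[!duplicated(run_id)]
  last <- tq[!duplicated(run_id, fromLast = TRUE)]
  n <- tabulate(run_id)
  span <- last + grid_seconds - first
  keep <- n >= min_epochs & span >= min_duration
  out <- data.table::data.table(
    start = first[keep], end = (last + grid_seconds)[keep],
    n_walk_epochs = n[keep], duration = span[keep]
  )
  if (inherits(epoch_start, "POSIXct")) {
    out[, `:=`(start = as.POSIXct(start, tz = "UTC", origin = "1970-01-01"),
               end = as.POSIXct(end, tz = "UTC", origin = "1970-01-01"))]
  }
  out[]
}

.empty_bouts <- function(epoch_start) {
  if (inherits(epoch_start, "POSIXct")) {
    z <- as.POSIXct(numeric(0), tz = "UTC", origin = "1970-01-01")
  } else z <- numeric(0)
  data.table::data.table(start = z, end = z, n_walk_epochs = integer(0),
                         duration = numeric(0))
}
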