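## Epoch-level I/O: reading, validating and writing 10-second step streams.
##
## An epoch table is a data.table with one row per
## (participant_id, device, epoch_start) carrying a step count and a worn
## flag.  Timestamps are epoch *starts*; the epoch [t, t + grid) belongs to
## the calendar day containing t (half-open convention, so midnight epochs
## are never double counted).

.WW_DEVICES <- c("study", "reference")

## Upper bound on steps per 10-s epoch: ~6 steps/s maximal human cadence.
.WW_MAX_STEPS_PER_EPOCH <- 60L

#' Read an epoch-level step-count table
#'
#' Reads a long-format CSV with one row per (participant, device,
#' epoch-start) and validates it against the epoch-grid invariants: all
#' timestamps on the `grid_seconds` grid, no duplicate keys, non-negative
#' step counts not exceeding 6 steps/s, and zero steps whenever the device
#' was not worn.
#'
#' @param path Path to a CSV with columns `participant_id`, `device`
#'   (`"study"` or `"reference"`), `epoch_start` (ISO-8601, assumed UTC when
#'   no offset is given), `steps`, and `worn` (`0/1/true/false`).
#' @param grid_seconds Epoch grid in seconds (default 10).
#' @return A `data.table` with columns `participant_id` (character),
#'   `device` (factor), `epoch_start` (POSIXct, UTC), `steps` (integer),
#'   `worn` (logical), sorted by (participant, device, epoch_start).
#' @export
#' @seealso [write_epochs()], [validate_epochs()]
read_epochs <- function(path, grid_seconds = 10L) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, colClasses = list(character = "participant_id"))
  need <- c("participant_id", "device", "epoch_start", "steps", "worn")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("epoch file is missing column(s): ", paste(miss, collapse = ", "))
  dt <- dt[, need, with = FALSE]
  if (!inherits(dt$epoch_start, "POSIXct")) {
    ts_chr <- as.character(dt$epoch_start)
    ts <- as.POSIXct(ts_chr, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS")
    alt <- is.na(ts)
    if (any(alt))
      ts[alt] <- as.POSIXct(ts_chr[alt], tz = "UTC",
                            format = "%Y-%m-%d %H:%M:%OS")
    if (anyNA(ts)) {
      bad <- which(is.na(ts))[1L]
      stop("malformed timestamp in row ", bad, ": '", dt$epoch_start[bad], "'")
    }
    dt[, epoch_start := ts]
  }
  attr(dt$epoch_start, "tzone") <- "UTC"
  if (is.character(dt$worn))
    dt[, worn := tolower(worn) %in% c("1", "true", "t", "yes")]
  dt[, `:=`(steps = as.integer(steps), worn = as.logical(worn))]
  validate_epochs(dt, grid_seconds = grid_seconds)
  dt[, device := factor(as.character(device), levels = .WW_DEVICES)]
  data.table::setkey(dt, participant_id, device, epoch_start)
  dt[]
}

#' Validate an epoch table against the grid invariants
#'
#' @param dt A data.table with epoch columns (see [read_epochs()]).
#' @param grid_seconds Epoch grid in seconds.
#' @return `dt`, invisibly, if valid; otherwise an error naming the first
#'   offending row.
#' @export
validate_epochs <- function(dt, grid_seconds = 10L) {
  dev <- as.character(dt$device)
  if (!all(dev %in% .WW_DEVICES)) {
    bad <- which(!dev %in% .WW_DEVICES)[1L]
    stop("row ", bad, ": unknown device '", dev[bad],
         "' (expected 'study' or 'reference')")
  }
  off <- as.numeric(dt$epoch_start) %% grid_seconds
  if (any(off != 0)) {
    bad <- which(off != 0)[1L]
    stop("row ", bad, ": epoch_start ", format(dt$epoch_start[bad]),
         " is not aligned to the ", grid_seconds, "-second grid")
  }
  if (anyNA(dt$steps) || any(dt$steps < 0L)) {
    bad <- which(is.na(dt$steps) | dt$steps < 0L)[1L]
    stop("row ", bad, ": negative or missing step count")
  }
  if (any(dt$steps > .WW_MAX_STEPS_PER_EPOCH)) {
    bad <- which(dt$steps > .WW_MAX_STEPS_PER_EPOCH)[1L]
    stop("row ", bad, ": ", dt$steps[bad], " steps exceeds the ",
         .WW_MAX_STEPS_PER_EPOCH, "-step epoch cap")
  }
  if (any(!dt$worn & dt$steps > 0L)) {
    bad <- which(!dt$worn & dt$steps > 0L)[1L]
    stop("row ", bad, ": nonzero steps on a not-worn epoch")
  }
  dup <- duplicated(dt, by = c("participant_id", "device", "epoch_start"))
  if (any(dup)) {
    bad <- which(dup)[1L]
    stop("row ", bad, ": duplicate (participant, device, epoch_start) key (",
         dt$participant_id[bad], ", ", dev[bad], ", ",
         format(dt$epoch_start[bad]), ")")
  }
  invisible(dt)
}

#' Write an epoch table to CSV
#'
#' Inverse of [read_epochs()]: `read_epochs(write_epochs(dt, f))` returns a
#' table identical to `dt` up to row order.
#'
#' @param dt Epoch data.table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(dt, path) {
  out <- data.table::copy(dt)
  out[, `:=`(
    epoch_start = format(epoch_start, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    worn = as.integer(worn),
    device = as.character(device)
  )]
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read participant metadata (gender and height)
#'
#' @param path CSV with columns `participant_id`, `gender`
#'   (`female`/`male`/`unspecified`), `height_m` (meters; may be empty).
#' @return data.table keyed by `participant_id` with `gender` (factor) and
#'   `height_m` (numeric, NA when absent).
#' @export
read_participant_meta <- function(path) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, colClasses = list(character = "participant_id"))
  need <- c("participant_id", "gender", "height_m")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("metadata file is missing column(s): ", paste(miss, collapse = ", "))
  dt <- dt[, need, with = FALSE]
  dt[, gender := as.character(gender)]
  dt[is.na(gender) | gender == "", gender := "unspecified"]
  if (!all(dt$gender %in% c("female", "male", "unspecified")))
    stop("gender must be one of female/male/unspecified")
  dt[, `:=`(gender = factor(gender, levels = c("female", "male", "unspecified")),
            height_m = as.numeric(height_m))]
  ok <- is.na(dt$height_m) | (dt$height_m > 0.5 & dt$height_m < 2.5)
  if (!all(ok))
    stop("row ", which(!ok)[1L], ": height_m outside the plausible (0.5, 2.5) m range")
  if (anyDuplicated(dt$participant_id))
    stop("duplicate participant_id in metadata")
  data.table::setkey(dt, participant_id)
  dt[]
}

#' Hours of device wear in a set of epochs
#'
#' Wear time is taken from the explicit `worn` flag (wear detection itself
#' is upstream of this pipeline): each worn epoch contributes
#' `grid_seconds` seconds.
#'
#' @param day_epochs Epoch data.table for a single participant-day-device
#'   (enforced), or a logical `worn` vector.
#' @param grid_seconds Epoch grid in seconds.
#' @return Wear time in hours, in `[0, 24]`.
#' @export
#' @examples
#' wear_hours(rep(TRUE, 2880))  # 8 hours
wear_hours <- function(day_epochs, grid_seconds = 10L) {
  if (is.logical(day_epochs))
    return(sum(day_epochs) * grid_seconds / 3600)
  if (nrow(day_epochs) == 0L) return(0)
  if (data.table::uniqueN(day_epochs$participant_id) > 1L ||
      data.table::uniqueN(as.character(day_epochs$device)) > 1L ||
      data.table::uniqueN(as.Date(day_epochs$epoch_start, tz = "UTC")) > 1L)
    stop("wear_hours() expects epochs from a single participant-day-device")
  sum(day_epochs$worn) * grid_seconds / 3600
}
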