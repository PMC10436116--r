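## Independent oracles used across the suite.  These deliberately take a
## different route than the package implementations: the bout oracle is a
## direct epoch-by-epoch scan; the ICC oracle computes the Pearson
## correlation of the pairs entered in both orderings; the agreement-metric
## oracles use their textbook formulas directly.

## Brute-force walking-bout scan: walk over qualifying epochs, chain while
## the wall-clock interruption is <= max_gap, then apply the minimum
## qualifying-epoch and span rules.
oracle_bouts <- function(t, steps, walk_threshold = 6, max_gap = 20,
                         min_duration = 30, grid = 10) {
  t <- as.numeric(t)
  out <- list()
  cur_first <- NA_real_; cur_last <- NA_real_; cur_n <- 0L
  flush <- function() {
    if (cur_n >= ceiling(min_duration / grid) &&
        (cur_last + grid - cur_first) >= min_duration)
      out[[length(out) + 1L]] <<- data.frame(
        start = cur_first, end = cur_last + grid, n_walk_epochs = cur_n,
        duration = cur_last + grid - cur_first)
  }
  for (i in seq_along(t)) {
    if (steps[i] < walk_threshold) next
    if (cur_n == 0L) {
      cur_first <- t[i]; cur_last <- t[i]; cur_n <- 1L
    } else if (t[i] - (cur_last + grid) <= max_gap) {
      cur_last <- t[i]; cur_n <- cur_n + 1L
    } else {
      flush()
      cur_first <- t[i]; cur_last <- t[i]; cur_n <- 1L
    }
  }
  if (cur_n > 0L) flush()
  if (length(out) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_walk_epochs = integer(0), duration = numeric(0)))
  do.call(rbind, out)
}

## Fisher ICC oracle: Pearson correlation of the doubled data (each pair in
## both orderings), via base R cor().
oracle_fisher_icc <- function(x, y) {
  stats::cor(c(x, y), c(y, x))
}

## Direct-formula agreement metrics.
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
oracle_me <- function(x, y) sum(x - y) / length(x)
oracle_mae <- function(x, y) sum(abs(x - y)) / length(x)

## Random one-day epoch sequence on the 10-s grid with missing epochs and a
## mix of sub- and supra-threshold step counts.
random_epoch_day <- function(n_slots = 80L, p_present = 0.8,
                             t0 = as.numeric(as.POSIXct("2024-05-01 10:00:00",
                                                        tz = "UTC"))) {
  keep <- runif(n_slots) < p_present
  t <- t0 + (which(keep) - 1L) * 10
  ## steps concentrated around the walk threshold to stress the gap rules
  steps <- sample(c(0L, 0L, 1L, 4L, 5L, 6L, 7L, 8L, 12L, 20L),
                  length(t), replace = TRUE)
  list(t = t, steps = steps)
}

## One-way ANOVA variance-component decomposition of a balanced
## participant x day table (oracle for the simulator's components).
oracle_anova_components <- function(values, participant) {
  participant <- factor(participant)
  n_i <- table(participant)
  stopifnot(length(unique(n_i)) == 1L)
  n <- unname(n_i[1L]); P <- nlevels(participant)
  gm <- mean(values)
  pm <- tapply(values, participant, mean)
  msb <- n * sum((pm - gm)^2) / (P - 1)
  msw <- sum((values - pm[participant])^2) / (P * (n - 1))
  c(between = (msb - msw) / n, within = msw)
}
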