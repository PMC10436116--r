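## End-to-end entry points mirroring the command-line interfaces in
## inst/cli/: simulate -> epochs CSV; epochs CSV -> agreement report;
## epochs CSV -> reliability curve.

#' Run the accuracy (two-device agreement) analysis on an epoch file
#'
#' Reads epochs (and optional participant metadata), computes daily
#' measures for both devices, applies the accuracy-day filter (>= `min_wear`
#' hours of wear and > `min_steps` steps on both devices), and writes the
#' agreement report.
#'
#' @param epochs_path Epoch CSV (see [read_epochs()]).
#' @param meta_path Optional metadata CSV (see [read_participant_meta()]).
#' @param out_dir Output directory; created if missing.  Files written:
#'   `agreement_metrics.csv` (one row per measure), `agreement_report.json`
#'   (metrics plus run parameters), and `bland_altman_<measure>.csv` point
#'   sets.
#' @param n_boot,level,seed Bootstrap settings (see [agreement_report()]).
#' @param min_wear,min_steps Day filter (see [filter_accuracy_days()]).
#' @param tz Calendar-day timezone.
#' @return The [agreement_report()] list, invisibly.
#' @export
run_accuracy_analysis <- function(epochs_path, meta_path = NULL, out_dir,
                                  n_boot = 1000L, level = 0.95, seed = 1L,
                                  min_wear = 8, min_steps = 100,
                                  tz = "UTC") {
  epochs <- read_epochs(epochs_path)
  meta <- if (!is.null(meta_path)) read_participant_meta(meta_path)
  daily <- compute_daily_measures(epochs, meta = meta, tz = tz)
  kept <- filter_accuracy_days(daily, min_wear = min_wear,
                               min_steps = min_steps)
  rep <- agreement_report(kept, n_boot = n_boot, level = level, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(rep$metrics, file.path(out_dir, "agreement_metrics.csv"),
                     na = "")
  for (m in names(rep$bland_altman))
    data.table::fwrite(rep$bland_altman[[m]],
                       file.path(out_dir, paste0("bland_altman_", m, ".csv")))
  jsonlite::write_json(
    list(parameters = list(n_boot = n_boot, level = level, seed = seed,
                           min_wear_hours = min_wear, min_steps = min_steps,
                           icc_type = "fisher",
                           pearson_p = "two-sided, participant-days treated as independent",
                           step_length_k = as.list(.WW_STEP_LENGTH_K)),
         metrics = rep$metrics),
    file.path(out_dir, "agreement_report.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(rep)
}

#' Run the time-to-reliability analysis on an epoch file
#'
#' Reads epochs, computes daily measures for the chosen device, and writes
#' the reliability curve (ICC by aggregation scope) and the
#' time-to-reliability summary.
#'
#' @inheritParams run_accuracy_analysis
#' @param device Which device's stream to analyze (default `"study"`).
#' @param max_scope Largest aggregation scope in days (default 30).
#' @param threshold Reliability threshold on the ICC (default 0.75).
#' @param min_daily_wear,min_wear_fraction Window eligibility rule (see
#'   [eligible_participants()]).
#' @param n_boot Bootstrap replicates per scope for the CI.
#' @return The [reliability_curve()] table, invisibly.  Files written:
#'   `reliability_curve.csv` and `time_to_reliability.json`.
#' @export
run_reliability_analysis <- function(epochs_path, meta_path = NULL, out_dir,
                                     device = "study", max_scope = 30L,
                                     threshold = 0.75, min_daily_wear = 12,
                                     min_wear_fraction = 0.5,
                                     n_boot = 200L, level = 0.95, seed = 1L,
                                     tz = "UTC") {
  epochs <- read_epochs(epochs_path)
  meta <- if (!is.null(meta_path)) read_participant_meta(meta_path)
  daily <- compute_daily_measures(epochs, meta = meta, tz = tz)
  sel <- as.character(daily[["device"]]) == device
  daily <- daily[which(sel)]
  curve <- reliability_curve(daily, scopes = seq_len(max_scope),
                             threshold = threshold,
                             min_daily_wear = min_daily_wear,
                             min_wear_fraction = min_wear_fraction,
                             n_boot = n_boot, level = level, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(curve, file.path(out_dir, "reliability_curve.csv"),
                     na = "")
  ttr <- attr(curve, "time_to_reliability")
  jsonlite::write_json(
    list(parameters = list(device = device, max_scope = max_scope,
                           threshold = threshold,
                           min_daily_wear_hours = min_daily_wear,
                           min_wear_fraction = min_wear_fraction,
                           n_boot = n_boot, seed = seed),
         time_to_reliability = ttr),
    file.path(out_dir, "time_to_reliability.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(curve)
}

#' Simulate a cohort and write it to CSV
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory; writes `epochs.csv`, `meta.csv`,
#'   `truth_daily.csv` and `truth_participants.csv`.
#' @return The [simulate_cohort()] list, invisibly.
#' @export
simulate_to_csv <- function(config = cohort_config(), out_dir) {
  sim <- simulate_cohort(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_epochs(sim$epochs, file.path(out_dir, "epochs.csv"))
  data.table::fwrite(sim$meta, file.path(out_dir, "meta.csv"))
  data.table::fwrite(sim$truth$daily, file.path(out_dir, "truth_daily.csv"),
                     na = "")
  data.table::fwrite(sim$truth$participants,
                     file.path(out_dir, "truth_participants.csv"))
  invisible(sim)
}
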