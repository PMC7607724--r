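#' Analyze a cohort of trials
#'
#' Applies the full single-trial chain (preprocess, pupil metrics,
#' behavioral scoring and optionally microsaccade detection) to every trial
#' and aggregates participant x condition tables for each dependent
#' measure.
#'
#' @param trials trial data.frame (see [read_trial_table()]).
#' @param traces list of [sample_trace()], parallel to `trials` rows.
#' @param cfg a [pipeline_config()].
#' @param microsaccades run microsaccade detection as well (slower).
#' @return list with `trial_results` (per-trial data.frame including
#'   `excluded`, `nan_fraction` and the metrics), `tables` (named list of
#'   condition tables: `accuracy`, `mean_dilation`, `peak_dilation`,
#'   `peak_latency`, and `ms_rate` when requested) and `exclusions` (count
#'   and percentage).
#' @export
analyze_cohort <- function(trials, traces, cfg = pipeline_config(),
                           microsaccades = TRUE) {
  n <- nrow(trials)
  stopifnot(length(traces) == n)
  excluded <- logical(n); nan_fraction <- numeric(n)
  mean_dilation <- rep(NA_real_, n); peak_dilation <- rep(NA_real_, n)
  peak_latency_s <- rep(NA_real_, n); ms_rate <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    dur <- trials$sentence_duration_s[i]
    clean <- preprocess_trial(traces[[i]], dur, cfg)
    excluded[i] <- clean$excluded
    nan_fraction[i] <- clean$nan_fraction
    if (!clean$excluded) {
      tm <- trial_metrics(clean, dur, cfg)
      mean_dilation[i] <- tm$mean_dilation
      peak_dilation[i] <- tm$peak_dilation
      peak_latency_s[i] <- tm$peak_latency_s
    }
    if (microsaccades) {
      ev <- detect_microsaccades(traces[[i]], cfg)
      rc <- rate_curve(ev, traces[[i]]$t, cfg)
      ms_rate[i] <- mean_rate(rc, dur, cfg)
    }
  }
  res <- data.frame(
    participant_id = trials$participant_id,
    clarity = trials$clarity, ambiguity = trials$ambiguity,
    excluded = excluded, nan_fraction = nan_fraction,
    mean_dilation = mean_dilation, peak_dilation = peak_dilation,
    peak_latency_s = peak_latency_s, ms_rate = ms_rate,
    is_correct = score_behavior(trials$response, trials$probe_related, cfg),
    stringsAsFactors = FALSE)

  tables <- list()
  tables$accuracy <- build_condition_table(
    data.frame(participant_id = res$participant_id, clarity = res$clarity,
               ambiguity = res$ambiguity,
               value = as.numeric(res$is_correct)), "accuracy")
  usable <- !res$excluded
  for (meas in c("mean_dilation", "peak_dilation", "peak_latency_s")) {
    tables[[sub("_s$", "", meas)]] <- build_condition_table(
      data.frame(participant_id = res$participant_id[usable],
                 clarity = res$clarity[usable],
                 ambiguity = res$ambiguity[usable],
                 value = res[[meas]][usable]), sub("_s$", "", meas))
  }
  if (microsaccades) {
    tables$ms_rate <- build_condition_table(
      data.frame(participant_id = res$participant_id, clarity = res$clarity,
                 ambiguity = res$ambiguity, value = res$ms_rate), "ms_rate")
  }
  list(trial_results = res, tables = tables,
       exclusions = list(n_excluded = sum(res$excluded),
                         pct_excluded = 100 * mean(res$excluded)))
}

#' Simulate and analyze one experiment end to end
#'
#' Convenience wrapper: [simulate_experiment()], [analyze_cohort()], then a
#' [rmanova_2x2()] for every dependent measure.
#'
#' @param sim_cfg a [sim_config()].
#' @param cfg a [pipeline_config()].
#' @param experiment experiment label.
#' @param microsaccades run microsaccade detection.
#' @return list with the simulation (`trials`, `traces`, `truth`), the
#'   cohort analysis (`tables`, `trial_results`, `exclusions`) and `anovas`
#'   (named list of [rmanova_2x2()] results).
#' @export
run_pipeline <- function(sim_cfg = sim_config(), cfg = pipeline_config(),
                         experiment = 1L, microsaccades = TRUE) {
  sim <- simulate_experiment(sim_cfg, experiment = experiment)
  ana <- analyze_cohort(sim$trials, sim$traces, cfg,
                        microsaccades = microsaccades)
  anovas <- lapply(ana$tables, rmanova_2x2)
  list(trials = sim$trials, traces = sim$traces, truth = sim$truth,
       trial_results = ana$trial_results, tables = ana$tables,
       exclusions = ana$exclusions, anovas = anovas)
}

#' Write cohort artifacts to a directory
#'
#' Writes the per-trial results, one condition-table CSV per measure and a
#' JSON stats report (requires the jsonlite package).
#'
#' @param result output of [run_pipeline()] or [analyze_cohort()] plus
#'   `anovas`.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$trial_results,
                   file.path(dir, "trial_results.csv"), row.names = FALSE)
  for (nm in names(result$tables))
    utils::write.csv(result$tables[[nm]],
                     file.path(dir, paste0("table_", nm, ".csv")),
                     row.names = FALSE)
  if (!is.null(result$anovas) &&
      requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(result$anovas, file.path(dir, "stats_report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
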