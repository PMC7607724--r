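#' Sentence-locked analysis window
#'
#' The window over which mean/peak dilation, peak latency and microsaccade
#' rate are measured: from `metric_pre_s` (0.5 s) after sentence onset to
#' `metric_post_s` (1 s) after sentence offset, in onset-relative seconds.
#'
#' @param sentence_duration_s sentence duration in seconds (> 0 and long
#'   enough that the window is nonempty).
#' @param cfg a [pipeline_config()].
#' @return numeric `c(t_start, t_end)`.
#' @export
metric_window <- function(sentence_duration_s, cfg = pipeline_config()) {
  if (!is.finite(sentence_duration_s) || sentence_duration_s <= 0)
    stop("sentence_duration_s must be positive", call. = FALSE)
  w <- c(cfg$metric_pre_s, sentence_duration_s + cfg$metric_post_s)
  if (w[2] <= w[1])
    stop("metric window is empty for this sentence duration", call. = FALSE)
  w
}

#' Per-trial pupil metrics
#'
#' From a preprocessed (baseline-corrected) trial: mean dilation is the
#' average corrected pupil area over the metric window; peak dilation is the
#' maximum in that window; peak latency is the time of that maximum (first
#' occurrence on ties), relative to sentence onset.
#'
#' @param clean a `clean_trial` from [preprocess_trial()] (not excluded).
#' @param sentence_duration_s sentence duration in seconds.
#' @param cfg a [pipeline_config()].
#' @return list with `mean_dilation`, `peak_dilation`, `peak_latency_s`.
#' @export
trial_metrics <- function(clean, sentence_duration_s,
                          cfg = pipeline_config()) {
  if (isTRUE(clean$excluded))
    stop("trial is excluded; no metrics can be computed", call. = FALSE)
  w <- metric_window(sentence_duration_s, cfg)
  tr <- clean$trace
  inwin <- tr$t >= w[1] - 1e-12 & tr$t <= w[2] + 1e-12
  if (!any(inwin)) stop("metric window contains no samples", call. = FALSE)
  p <- tr$pupil[inwin]
  tt <- tr$t[inwin]
  i <- which.max(p)  # first occurrence on ties
  list(mean_dilation = mean(p), peak_dilation = p[i], peak_latency_s = tt[i])
}

#' Score the semantic-relatedness response
#'
#' Correct iff the keypress matches the probe's ground-truth relatedness
#' ("related" for a related probe, "unrelated" otherwise).  Timeouts
#' (`response == "none"`) are scored incorrect under the default policy, or
#' `NA` under `none_policy = "exclude"`.
#'
#' @param response one of `"related"`, `"unrelated"`, `"none"`.
#' @param probe_related logical ground truth.
#' @param cfg a [pipeline_config()].
#' @return logical (or `NA` for excluded timeouts).
#' @export
score_behavior <- function(response, probe_related, cfg = pipeline_config()) {
  expected <- ifelse(probe_related, "related", "unrelated")
  correct <- response == expected
  if (cfg$none_policy == "exclude") {
    correct[response == "none"] <- NA
  } else {
    correct[response == "none"] <- FALSE
  }
  correct
}

cell_label <- function(clarity, ambiguity) {
  paste(ambiguity, sub("_snr$", "", clarity), sep = "_")
}

condition_cells <- c("LA_high", "HA_high", "LA_low", "HA_low")

#' Participant-by-condition table of one dependent measure
#'
#' Averages a per-trial measure within each of the four Clarity x Ambiguity
#' cells, separately per participant.  Participants lacking a usable trial
#' in any cell are dropped listwise with a warning (a complete matrix is
#' required downstream).
#'
#' @param df data.frame with columns `participant_id`, `clarity`,
#'   `ambiguity` and `value` (one row per usable trial).
#' @param measure name of the measure (stored as an attribute).
#' @return data.frame with `participant` plus columns `LA_high`, `HA_high`,
#'   `LA_low`, `HA_low`; attributes `measure` and `n_trials` (per-cell trial
#'   counts).
#' @export
build_condition_table <- function(df, measure = "value") {
  stopifnot(all(c("participant_id", "clarity", "ambiguity", "value")
                %in% names(df)))
  df <- df[!is.na(df$value), ]
  if (!nrow(df)) stop("no usable trials", call. = FALSE)
  df$cell <- cell_label(df$clarity, df$ambiguity)
  parts <- unique(df$participant_id)
  means <- tapply(df$value, list(df$participant_id, df$cell), mean)
  counts <- tapply(df$value, list(df$participant_id, df$cell), length)
  full <- matrix(NA_real_, nrow = length(parts), ncol = 4,
                 dimnames = list(as.character(parts), condition_cells))
  nmat <- matrix(0L, nrow = length(parts), ncol = 4,
                 dimnames = list(as.character(parts), condition_cells))
  for (cl in intersect(condition_cells, colnames(means))) {
    full[rownames(means), cl] <- means[, cl]
    cnt <- counts[, cl]
    cnt[is.na(cnt)] <- 0L
    nmat[rownames(counts), cl] <- cnt
  }
  complete <- stats::complete.cases(full)
  if (!any(complete))
    stop("no participant has usable trials in all four cells", call. = FALSE)
  if (any(!complete))
    warning(sprintf("dropping %d participant(s) with empty cells: %s",
                    sum(!complete),
                    paste(rownames(full)[!complete], collapse = ", ")),
            call. = FALSE)
  out <- data.frame(participant = rownames(full)[complete],
                    full[complete, , drop = FALSE],
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "measure") <- measure
  attr(out, "n_trials") <- nmat[complete, , drop = FALSE]
  out
}
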