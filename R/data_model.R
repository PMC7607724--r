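#' One trial's continuous eye-tracker recording
#'
#' A `sample_trace` holds the time base, pupil area, gaze position and
#' device-flagged blink intervals of one trial.  Time is in seconds relative
#' to sentence onset (onset = 0), so a trace typically spans a 3 s pre-onset
#' lead through 1.2 s past sentence offset.  The time base must be uniform at
#' `1/sampling_rate` to within 1e-9 s.
#'
#' @param t numeric vector of sample times (s, onset-relative), strictly
#'   increasing and uniformly spaced.
#' @param pupil pupil area in arbitrary tracker units; `NaN` marks missing.
#' @param gaze_x,gaze_y gaze position (degrees of visual angle by convention;
#'   the unit is recorded, never converted).
#' @param blink_intervals two-column matrix (or data.frame) of closed blink
#'   intervals `(start_s, end_s)` flagged by the tracker; may have 0 rows.
#' @param sampling_rate sampling rate in Hz.
#' @param gaze_unit character tag for the gaze unit.
#' @return an object of class `sample_trace`.
#' @export
sample_trace <- function(t, pupil, gaze_x, gaze_y,
                         blink_intervals = matrix(numeric(0), ncol = 2),
                         sampling_rate = 500,
                         gaze_unit = "deg") {
  t <- as.numeric(t)
  n <- length(t)
  if (length(pupil) != n || length(gaze_x) != n || length(gaze_y) != n)
    stop("pupil, gaze_x and gaze_y must have the same length as t",
         call. = FALSE)
  dt <- 1 / sampling_rate
  if (n > 1) {
    steps <- diff(t)
    bad <- which(abs(steps - dt) > 1e-9)
    if (length(bad))
      stop(sprintf(
        "non-uniform time base: step %d (t=%.6f -> t=%.6f) differs from 1/%g s",
        bad[1], t[bad[1]], t[bad[1] + 1], sampling_rate), call. = FALSE)
  }
  bl <- as.matrix(blink_intervals)
  if (length(bl) == 0) bl <- matrix(numeric(0), ncol = 2)
  if (ncol(bl) != 2)
    stop("blink_intervals must have two columns (start_s, end_s)",
         call. = FALSE)
  storage.mode(bl) <- "double"
  colnames(bl) <- c("start_s", "end_s")
  if (nrow(bl)) {
    if (any(bl[, 2] < bl[, 1]))
      stop("blink intervals must have end_s >= start_s", call. = FALSE)
    if (any(bl[, 1] < t[1] - 1e-9) || any(bl[, 2] > t[n] + 1e-9))
      stop("blink intervals must lie within the recorded span", call. = FALSE)
  }
  structure(list(t = t, pupil = as.numeric(pupil),
                 gaze_x = as.numeric(gaze_x), gaze_y = as.numeric(gaze_y),
                 blink_intervals = bl, sampling_rate = sampling_rate,
                 gaze_unit = gaze_unit),
            class = "sample_trace")
}

#' @export
print.sample_trace <- function(x, ...) {
  cat(sprintf("<sample_trace> %d samples @ %g Hz, t in [%.3f, %.3f] s, %d blink(s)\n",
              length(x$t), x$sampling_rate, x$t[1], x$t[length(x$t)],
              nrow(x$blink_intervals)))
  invisible(x)
}

trial_required_cols <- c("participant_id", "experiment", "block",
                         "clarity", "ambiguity",
                         "sentence_onset_s", "sentence_duration_s",
                         "probe_related", "response")

clarity_levels <- c("high_snr", "low_snr")
ambiguity_levels <- c("LA", "HA")
response_levels <- c("related", "unrelated", "none")

#' Read a trial-metadata table
#'
#' Reads a CSV whose header names every trial field: `participant_id`,
#' `experiment` (1 or 2), `block`, `clarity` (`high_snr`/`low_snr`),
#' `ambiguity` (`LA`/`HA`), `sentence_onset_s`, `sentence_duration_s`,
#' `probe_related` (logical), `response` (`related`/`unrelated`/`none`) and
#' optionally `response_time_s`.  Unknown columns are preserved.  Row order
#' is preserved; no row is silently dropped.
#'
#' @param path path to a CSV file.
#' @return a data.frame, one row per trial.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_required_cols, names(df))
  if (length(missing_cols))
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  check_enum <- function(col, levels) {
    bad <- which(!df[[col]] %in% levels)
    if (length(bad))
      stop(sprintf("row %d: invalid %s value '%s' (expected one of %s)",
                   bad[1], col, df[[col]][bad[1]],
                   paste(levels, collapse = ", ")), call. = FALSE)
  }
  check_enum("clarity", clarity_levels)
  check_enum("ambiguity", ambiguity_levels)
  check_enum("response", response_levels)
  if (!is.logical(df$probe_related)) {
    pr <- df$probe_related
    df$probe_related <- as.logical(pr)
    bad <- which(is.na(df$probe_related) & !is.na(pr))
    if (length(bad))
      stop(sprintf("row %d: invalid probe_related value '%s'",
                   bad[1], pr[bad[1]]), call. = FALSE)
  }
  if (!"response_time_s" %in% names(df)) df$response_time_s <- NA_real_
  none_with_rt <- which(df$response == "none" & !is.na(df$response_time_s))
  if (length(none_with_rt))
    stop(sprintf("row %d: response 'none' must not carry a response time",
                 none_with_rt[1]), call. = FALSE)
  df
}

#' Write a trial-metadata table
#'
#' @param trials data.frame of trials (as returned by [read_trial_table()]
#'   or [simulate_experiment()]).
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read one trial's samples (and optional blink table)
#'
#' The samples file is a CSV with columns `t,pupil,gaze_x,gaze_y`; missing
#' pupil samples are spelled `NaN`.  Blink intervals come from a companion
#' CSV with columns `start_s,end_s`.  Timestamps must be uniform at
#' `1/sampling_rate`; a dropped sample is reported with its index.
#'
#' @param path samples CSV path.
#' @param blink_path optional blink CSV path.
#' @param sampling_rate sampling rate in Hz used to validate the time base.
#' @return a [sample_trace()].
#' @export
read_samples <- function(path, blink_path = NULL, sampling_rate = 500) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "pupil", "gaze_x", "gaze_y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("samples file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  blinks <- matrix(numeric(0), ncol = 2)
  if (!is.null(blink_path) && file.exists(blink_path)) {
    bdf <- utils::read.csv(blink_path, stringsAsFactors = FALSE)
    if (!all(c("start_s", "end_s") %in% names(bdf)))
      stop("blink file must have columns start_s,end_s", call. = FALSE)
    blinks <- as.matrix(bdf[, c("start_s", "end_s")])
  }
  sample_trace(df$t, df$pupil, df$gaze_x, df$gaze_y,
               blink_intervals = blinks, sampling_rate = sampling_rate)
}

#' Write one trial's samples (and blink table)
#'
#' @param trace a [sample_trace()].
#' @param path destination samples CSV.
#' @param blink_path optional destination for the blink-interval CSV.
#' @param digits significant digits used for the text serialization.
#' @return `path`, invisibly.
#' @export
write_samples <- function(trace, path, blink_path = NULL, digits = 15) {
  df <- data.frame(t = trace$t, pupil = trace$pupil,
                   gaze_x = trace$gaze_x, gaze_y = trace$gaze_y)
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  out <- data.frame(lapply(df, fmt), stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(blink_path)) {
    bdf <- as.data.frame(trace$blink_intervals)
    utils::write.csv(bdf, blink_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
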