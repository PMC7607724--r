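# median of a finite vector without dispatch overhead (same convention as
# stats::median: mean of the two central order statistics for even n)
fast_median <- function(x) {
  n <- length(x)
  h <- (n + 1L) %/% 2L
  if (n %% 2L) {
    sort(x, partial = h)[h]
  } else {
    s <- sort(x, partial = c(h, h + 1L))
    (s[h] + s[h + 1L]) / 2
  }
}

# linear interpolation over non-finite entries, constant extension at the
# edges; x must have >= 2 finite entries
na_interp <- function(t, x) {
  miss <- which(!is.finite(x))
  if (!length(miss)) return(x)
  fin <- which(is.finite(x))
  tf <- t[fin]; xf <- x[fin]
  K <- length(fin)
  j <- findInterval(t[miss], tf)
  lo <- j < 1L; hi <- j >= K
  mid <- !(lo | hi)
  out <- numeric(length(miss))
  out[lo] <- xf[1]
  out[hi] <- xf[K]
  if (any(mid)) {
    jm <- j[mid]
    tm <- t[miss][mid]
    out[mid] <- xf[jm] + (xf[jm + 1L] - xf[jm]) *
      (tm - tf[jm]) / (tf[jm + 1L] - tf[jm])
  }
  x[miss] <- out
  x
}

#' Blank out blink artifacts
#'
#' For each device-flagged blink, pupil samples from `blink_pre_s` (50 ms)
#' before its start to `blink_post_s` (200 ms) after its end are set to
#' `NaN` (closed interval on the sample grid).  Overlapping expanded windows
#' merge naturally.  Gaze channels are untouched.
#'
#' @param trace a [sample_trace()].
#' @param cfg a [pipeline_config()].
#' @return the trace with blink-contaminated pupil samples set to `NaN`.
#' @export
mask_blinks <- function(trace, cfg = pipeline_config()) {
  bl <- trace$blink_intervals
  if (!nrow(bl)) return(trace)
  for (i in seq_len(nrow(bl))) {
    lo <- bl[i, 1] - cfg$blink_pre_s
    hi <- bl[i, 2] + cfg$blink_post_s
    trace$pupil[trace$t >= lo - 1e-12 & trace$t <= hi + 1e-12] <- NaN
  }
  trace
}

#' Blank out pupil outliers
#'
#' Samples whose pupil area differs from the trial median by more than
#' `mad_k` times the raw median absolute deviation (no normal-consistency
#' scaling) are set to `NaN`.  The median and MAD are computed over the
#' finite samples of the whole recorded trial, so blink-masked samples do
#' not contribute.  The comparison is strict, so a constant trace (MAD 0)
#' loses no samples.
#'
#' @inheritParams mask_blinks
#' @return the trace with outlier samples set to `NaN`.
#' @export
mask_outliers <- function(trace, cfg = pipeline_config()) {
  p <- trace$pupil
  fin <- is.finite(p)
  if (!any(fin)) stop("all pupil samples are missing", call. = FALSE)
  med <- fast_median(p[fin])
  mad_raw <- fast_median(abs(p[fin] - med))
  out <- fin & (abs(p - med) > cfg$mad_k * mad_raw)
  trace$pupil[out] <- NaN
  trace
}

#' Linearly interpolate missing pupil samples
#'
#' Interior `NaN` runs are replaced by linear interpolation between the
#' bracketing finite samples; leading/trailing runs are filled by constant
#' extension of the nearest finite value.
#'
#' @param trace a [sample_trace()].
#' @return the trace with a fully finite pupil channel.
#' @export
interpolate_gaps <- function(trace) {
  p <- trace$pupil
  fin <- is.finite(p)
  if (sum(fin) < 2)
    stop("need at least 2 finite pupil samples to interpolate", call. = FALSE)
  if (all(fin)) return(trace)
  trace$pupil <- na_interp(trace$t, p)
  trace
}

#' Trial exclusion by missing-data fraction
#'
#' Computes the fraction of `NaN` pupil samples (on the pre-interpolation
#' mask) among samples with `t` in `[-exclusion_pre_s, offset +
#' exclusion_post_s]`, i.e. from 0.5 s before sentence onset to 1 s after
#' sentence offset.  The trial is excluded iff the fraction strictly
#' exceeds `nan_frac_max` (40%).
#'
#' @param trace the trace *before* interpolation.
#' @param sentence_duration_s the trial's sentence duration (s).
#' @param cfg a [pipeline_config()].
#' @return list with `nan_fraction` and logical `excluded`.
#' @export
exclusion_decision <- function(trace, sentence_duration_s,
                               cfg = pipeline_config()) {
  lo <- -cfg$exclusion_pre_s
  hi <- sentence_duration_s + cfg$exclusion_post_s
  if (lo < trace$t[1] - 1e-9 || hi > trace$t[length(trace$t)] + 1e-9)
    stop("exclusion window extends beyond the recorded span", call. = FALSE)
  inwin <- trace$t >= lo - 1e-12 & trace$t <= hi + 1e-12
  frac <- mean(!is.finite(trace$pupil[inwin]))
  list(nan_fraction = frac, excluded = frac > cfg$nan_frac_max)
}

# Kaiser-window FIR low-pass taps, DC gain exactly 1; memoized on the
# design parameters since the design is re-used for every trial.
.tap_cache <- new.env(parent = emptyenv())
kaiser_lowpass_taps <- function(sampling_rate, cfg) {
  key <- paste(sampling_rate, cfg$lp_cutoff_hz, cfg$fir_length,
               cfg$kaiser_beta, sep = "|")
  h <- .tap_cache[[key]]
  if (is.null(h)) {
    h <- signal::fir1(cfg$fir_length - 1L,
                      cfg$lp_cutoff_hz / (sampling_rate / 2),
                      type = "low",
                      window = signal::kaiser(cfg$fir_length,
                                              cfg$kaiser_beta))
    h <- h / sum(h)
    .tap_cache[[key]] <- h
  }
  h
}

#' Zero-phase Kaiser-window FIR low-pass
#'
#' Applies the 201-tap, 10 Hz (at the trace's sampling rate) linear-phase
#' FIR designed by the Kaiser-window method.  The symmetric filter is
#' applied centred (group delay compensated), with reflection padding at the
#' edges, so the output is time-aligned with the input and the DC gain is
#' exactly 1.
#'
#' @param trace a [sample_trace()] with a finite pupil channel.
#' @param cfg a [pipeline_config()].
#' @return the filtered trace.
#' @export
lowpass_10hz <- function(trace, cfg = pipeline_config()) {
  x <- trace$pupil
  n <- length(x)
  if (n <= cfg$fir_length)
    stop(sprintf("trace (%d samples) is not longer than the filter (%d taps)",
                 n, cfg$fir_length), call. = FALSE)
  if (any(!is.finite(x)))
    stop("pupil must be finite before filtering (interpolate first)",
         call. = FALSE)
  h <- kaiser_lowpass_taps(trace$sampling_rate, cfg)
  half <- (cfg$fir_length - 1L) %/% 2L
  padded <- c(x[(half + 1):2], x, x[(n - 1):(n - half)])
  y <- stats::filter(padded, h, method = "convolution", sides = 2)
  trace$pupil <- as.numeric(y[(half + 1):(half + n)])
  trace
}

#' Baseline-correct a pupil trace
#'
#' Subtracts the mean pupil value over the baseline window (default -0.5 s
#' to 0 s, closed-open so the onset sample is not double counted) from every
#' sample.
#'
#' @inheritParams lowpass_10hz
#' @return list with the corrected `trace` and the subtracted
#'   `baseline_mean`.
#' @export
baseline_correct <- function(trace, cfg = pipeline_config()) {
  win <- cfg$baseline_window
  inwin <- trace$t >= win[1] - 1e-12 & trace$t < win[2] - 1e-12
  if (!any(inwin)) stop("baseline window contains no samples", call. = FALSE)
  b <- mean(trace$pupil[inwin])
  trace$pupil <- trace$pupil - b
  list(trace = trace, baseline_mean = b)
}

#' Preprocess one trial
#'
#' Runs the full single-trial chain in the canonical order: blink masking,
#' MAD outlier masking, linear interpolation, exclusion decision (on the
#' pre-interpolation missing mask), Kaiser FIR low-pass, baseline
#' correction.  If the trial is excluded, filtering and baseline correction
#' are skipped.
#'
#' @param trace a raw [sample_trace()].
#' @param sentence_duration_s the trial's sentence duration (s).
#' @param cfg a [pipeline_config()].
#' @return an object of class `clean_trial`: list with `trace` (corrected,
#'   or the interpolated trace if excluded), `baseline_mean`,
#'   `nan_fraction`, `n_interpolated`, `excluded`, `exclusion_reason`
#'   (`"none"` or `"nan_fraction"`).
#' @export
preprocess_trial <- function(trace, sentence_duration_s,
                             cfg = pipeline_config()) {
  st <- mask_blinks(trace, cfg)
  if (sum(is.finite(st$pupil)) < 2) {
    # effectively no usable pupil data: exclusion is forced
    dec <- exclusion_decision(st, sentence_duration_s, cfg)
    return(structure(list(trace = st, baseline_mean = NA_real_,
                          nan_fraction = dec$nan_fraction,
                          n_interpolated = sum(!is.finite(st$pupil)),
                          excluded = TRUE, exclusion_reason = "nan_fraction"),
                     class = "clean_trial"))
  }
  st <- mask_outliers(st, cfg)
  nan_mask <- !is.finite(st$pupil)
  dec <- exclusion_decision(st, sentence_duration_s, cfg)
  if (dec$excluded) {
    return(structure(list(trace = st, baseline_mean = NA_real_,
                          nan_fraction = dec$nan_fraction,
                          n_interpolated = sum(nan_mask),
                          excluded = TRUE, exclusion_reason = "nan_fraction"),
                     class = "clean_trial"))
  }
  st <- interpolate_gaps(st)
  st <- lowpass_10hz(st, cfg)
  bc <- baseline_correct(st, cfg)
  structure(list(trace = bc$trace, baseline_mean = bc$baseline_mean,
                 nan_fraction = dec$nan_fraction,
                 n_interpolated = sum(nan_mask),
                 excluded = FALSE, exclusion_reason = "none"),
            class = "clean_trial")
}
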