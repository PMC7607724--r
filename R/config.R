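#' Analysis configuration
#'
#' Collects every numeric parameter of the pupil / microsaccade analysis in
#' one validated object.  Defaults are the canonical analysis settings:
#' blink padding of 50 ms before and 200 ms after each device-flagged blink,
#' outlier rejection at 3 raw median absolute deviations, trial exclusion
#' when more than 40% of samples between 0.5 s before sentence onset and 1 s
#' after sentence offset are missing, a 201-tap 10 Hz Kaiser-window FIR
#' low-pass, a -0.5 to 0 s baseline window, and a metric window from 0.5 s
#' after onset to 1 s after offset.  Microsaccades use a relative velocity
#' threshold of 15 robust standard deviations, a 6 ms minimum duration and a
#' 0.02 s Gaussian rate kernel.
#'
#' @param blink_pre_s seconds of padding removed before each blink.
#' @param blink_post_s seconds of padding removed after each blink.
#' @param mad_k outlier threshold in multiples of the raw MAD.
#' @param nan_frac_max maximum tolerated missing fraction (strict: a trial is
#'   excluded only when the fraction exceeds this value).
#' @param exclusion_pre_s,exclusion_post_s the exclusion-window bounds,
#'   seconds before onset and after offset respectively.
#' @param lp_cutoff_hz low-pass cutoff in Hz.
#' @param fir_length FIR length in taps (odd).
#' @param kaiser_beta Kaiser window shape parameter (beta = 5 gives roughly
#'   50 dB sidelobe attenuation).
#' @param baseline_window length-2 numeric, baseline interval in seconds
#'   relative to sentence onset; treated as closed-open.
#' @param metric_pre_s,metric_post_s metric-window bounds, seconds after
#'   onset and after offset respectively.
#' @param ms_threshold_k velocity threshold in multiples of the robust SD.
#' @param ms_min_duration_s minimum microsaccade duration in seconds.
#' @param ms_kernel_sd_s SD of the Gaussian rate kernel in seconds.
#' @param ms_velocity_floor_deg_s floor on the robust velocity SD (deg/s) so
#'   noise-free traces do not produce a zero threshold.
#' @param ms_criterion `"elliptic"` (two-component ellipse) or `"speed"`
#'   (scalar speed against the radial threshold).
#' @param none_policy scoring of response timeouts: `"incorrect"` or
#'   `"exclude"`.
#' @return an object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(blink_pre_s = 0.05,
                            blink_post_s = 0.20,
                            mad_k = 3.0,
                            nan_frac_max = 0.40,
                            exclusion_pre_s = 0.5,
                            exclusion_post_s = 1.0,
                            lp_cutoff_hz = 10.0,
                            fir_length = 201L,
                            kaiser_beta = 5.0,
                            baseline_window = c(-0.5, 0),
                            metric_pre_s = 0.5,
                            metric_post_s = 1.0,
                            ms_threshold_k = 15.0,
                            ms_min_duration_s = 0.006,
                            ms_kernel_sd_s = 0.02,
                            ms_velocity_floor_deg_s = 0.01,
                            ms_criterion = c("elliptic", "speed"),
                            none_policy = c("incorrect", "exclude")) {
  ms_criterion <- match.arg(ms_criterion)
  none_policy <- match.arg(none_policy)
  cfg <- list(
    blink_pre_s = blink_pre_s, blink_post_s = blink_post_s,
    mad_k = mad_k, nan_frac_max = nan_frac_max,
    exclusion_pre_s = exclusion_pre_s, exclusion_post_s = exclusion_post_s,
    lp_cutoff_hz = lp_cutoff_hz, fir_length = as.integer(fir_length),
    kaiser_beta = kaiser_beta, baseline_window = baseline_window,
    metric_pre_s = metric_pre_s, metric_post_s = metric_post_s,
    ms_threshold_k = ms_threshold_k, ms_min_duration_s = ms_min_duration_s,
    ms_kernel_sd_s = ms_kernel_sd_s,
    ms_velocity_floor_deg_s = ms_velocity_floor_deg_s,
    ms_criterion = ms_criterion, none_policy = none_policy
  )
  problems <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(blink_pre_s >= 0 && blink_post_s >= 0,
      "blink_pre_s/blink_post_s must be nonnegative")
  chk(mad_k > 0, "mad_k must be positive")
  chk(is.numeric(nan_frac_max) && nan_frac_max > 0 && nan_frac_max < 1,
      "nan_frac_max must lie in (0, 1)")
  chk(exclusion_pre_s > 0 && exclusion_post_s > 0,
      "exclusion window bounds must be positive")
  chk(lp_cutoff_hz > 0, "lp_cutoff_hz must be positive")
  chk(cfg$fir_length %% 2L == 1L && cfg$fir_length >= 3L,
      "fir_length must be odd and >= 3")
  chk(kaiser_beta >= 0, "kaiser_beta must be nonnegative")
  chk(length(baseline_window) == 2 && baseline_window[1] < baseline_window[2],
      "baseline_window must be an increasing length-2 interval")
  chk(metric_pre_s >= 0 && metric_post_s >= 0,
      "metric window bounds must be nonnegative")
  chk(ms_threshold_k > 0, "ms_threshold_k must be positive")
  chk(ms_min_duration_s > 0, "ms_min_duration_s must be positive")
  chk(ms_kernel_sd_s > 0, "ms_kernel_sd_s must be positive")
  chk(ms_velocity_floor_deg_s > 0, "ms_velocity_floor_deg_s must be positive")
  if (length(problems))
    stop("invalid pipeline_config: ", paste(problems, collapse = "; "),
         call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
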