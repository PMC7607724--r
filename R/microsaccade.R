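#' Gaze velocity by a 5-point moving-window stencil
#'
#' `v[i] = (p[i+2] + p[i+1] - p[i-1] - p[i-2]) / (6 * dt)`, the standard
#' noise-suppressing differentiator for fixational eye-movement analysis.
#' It is exact for polynomials up to degree 2.  The first and last two
#' samples, and any sample whose stencil touches a non-finite gaze value,
#' are `NA`.
#'
#' @param trace a [sample_trace()].
#' @return list with `vx`, `vy` (deg/s, `NA` where undefined).
#' @export
gaze_velocity <- function(trace) {
  n <- length(trace$t)
  if (n < 5) stop("need at least 5 samples for the velocity stencil",
                  call. = FALSE)
  dt <- 1 / trace$sampling_rate
  stencil <- function(p) {
    v <- rep(NA_real_, n)
    i <- 3:(n - 2)
    v[i] <- (p[i + 2] + p[i + 1] - p[i - 1] - p[i - 2]) / (6 * dt)
    v
  }
  list(vx = stencil(trace$gaze_x), vy = stencil(trace$gaze_y))
}

# robust (median-based) SD of a velocity component
robust_velocity_sd <- function(v) {
  sqrt(max(stats::median(v^2) - stats::median(v)^2, 0))
}

#' Relative velocity thresholds
#'
#' Per component, the noise scale is the median-based robust estimator
#' `sigma^2 = median(v^2) - median(v)^2`; the detection threshold is
#' `ms_threshold_k` (15) times that scale.  A configurable floor
#' (`ms_velocity_floor_deg_s`) keeps the threshold positive on noise-free
#' synthetic traces.
#'
#' @param vx,vy velocity components (deg/s); `NA`s are ignored.
#' @param cfg a [pipeline_config()].
#' @return numeric `c(eta_x, eta_y)` in deg/s.
#' @export
velocity_threshold <- function(vx, vy, cfg = pipeline_config()) {
  ok <- is.finite(vx) & is.finite(vy)
  if (sum(ok) < 100)
    stop("need at least 100 valid velocity samples for threshold estimation",
         call. = FALSE)
  sx <- max(robust_velocity_sd(vx[ok]), cfg$ms_velocity_floor_deg_s)
  sy <- max(robust_velocity_sd(vy[ok]), cfg$ms_velocity_floor_deg_s)
  c(eta_x = cfg$ms_threshold_k * sx, eta_y = cfg$ms_threshold_k * sy)
}

expand_blink_windows <- function(trace, cfg) {
  bl <- trace$blink_intervals
  if (!nrow(bl)) return(bl)
  cbind(bl[, 1] - cfg$blink_pre_s, bl[, 2] + cfg$blink_post_s)
}

#' Detect microsaccades by a relative velocity threshold
#'
#' Candidate samples exceed the threshold ellipse
#' `(vx/eta_x)^2 + (vy/eta_y)^2 > 1` (or, with `ms_criterion = "speed"`,
#' scalar speed above the radial threshold).  Maximal candidate runs lasting
#' at least `ms_min_duration_s` (6 ms; a run of k samples persists k*dt)
#' become events.  Samples inside expanded blink windows are never
#' candidates, and events overlapping such windows are discarded.  Event
#' duration is `k*dt`, amplitude the net onset-to-offset gaze displacement,
#' peak velocity the maximum speed within the run.
#'
#' @param trace a [sample_trace()].
#' @param cfg a [pipeline_config()].
#' @return data.frame with columns `onset_s`, `offset_s`, `duration_s`,
#'   `amplitude_deg`, `peak_velocity` (possibly 0 rows).
#' @export
detect_microsaccades <- function(trace, cfg = pipeline_config()) {
  v <- gaze_velocity(trace)
  dt <- 1 / trace$sampling_rate
  valid <- is.finite(v$vx) & is.finite(v$vy)
  bw <- expand_blink_windows(trace, cfg)
  in_blink <- rep(FALSE, length(trace$t))
  if (nrow(bw)) {
    for (i in seq_len(nrow(bw)))
      in_blink <- in_blink |
        (trace$t >= bw[i, 1] - 1e-12 & trace$t <= bw[i, 2] + 1e-12)
  }
  eta <- velocity_threshold(v$vx[!in_blink], v$vy[!in_blink], cfg)
  crit <- rep(FALSE, length(trace$t))
  if (cfg$ms_criterion == "elliptic") {
    crit[valid] <- (v$vx[valid] / eta[1])^2 + (v$vy[valid] / eta[2])^2 > 1
  } else {
    crit[valid] <- sqrt(v$vx[valid]^2 + v$vy[valid]^2) >
      sqrt(eta[1]^2 + eta[2]^2) / sqrt(2)
  }
  crit[in_blink] <- FALSE
  r <- rle(crit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths * dt >= cfg$ms_min_duration_s - 1e-12)
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts))
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0), amplitude_deg = numeric(0),
                      peak_velocity = numeric(0)))
  ev <- lapply(seq_along(starts), function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    dx <- trace$gaze_x[i1] - trace$gaze_x[i0]
    dy <- trace$gaze_y[i1] - trace$gaze_y[i0]
    sp <- sqrt(v$vx[i0:i1]^2 + v$vy[i0:i1]^2)
    data.frame(onset_s = trace$t[i0],
               offset_s = trace$t[i0] + (i1 - i0 + 1L) * dt,
               duration_s = (i1 - i0 + 1L) * dt,
               amplitude_deg = sqrt(dx^2 + dy^2),
               peak_velocity = max(sp))
  })
  do.call(rbind, ev)
}

#' Microsaccade rate curve by Gaussian-kernel smoothing
#'
#' Each event contributes a unit-area Gaussian (SD `ms_kernel_sd_s` =
#' 0.02 s, zero phase lag) centred at its onset; contributions are summed on
#' the trace's time grid.  Units are events/s.
#'
#' @param events event data.frame from [detect_microsaccades()].
#' @param t uniform time grid (s).
#' @param cfg a [pipeline_config()].
#' @return list of class `rate_curve` with `t` and `rate`.
#' @export
rate_curve <- function(events, t, cfg = pipeline_config()) {
  rate <- numeric(length(t))
  if (nrow(events)) {
    for (on in events$onset_s)
      rate <- rate + stats::dnorm(t, mean = on, sd = cfg$ms_kernel_sd_s)
  }
  structure(list(t = t, rate = rate), class = "rate_curve")
}

#' Mean microsaccade rate over the metric window
#'
#' Arithmetic mean of the rate curve over the sentence-locked metric window
#' (0.5 s post onset to 1 s post offset), mirroring the pupil metrics.
#'
#' @param curve a [rate_curve()].
#' @param sentence_duration_s sentence duration (s).
#' @param cfg a [pipeline_config()].
#' @return mean rate in events/s.
#' @export
mean_rate <- function(curve, sentence_duration_s, cfg = pipeline_config()) {
  w <- metric_window(sentence_duration_s, cfg)
  inwin <- curve$t >= w[1] - 1e-12 & curve$t <= w[2] + 1e-12
  if (!any(inwin)) stop("metric window contains no samples", call. = FALSE)
  mean(curve$rate[inwin])
}

#' Match detected microsaccades to ground-truth events
#'
#' Greedy one-to-one matching by onset proximity within `tol_s`; used to
#' validate the detector against simulated ground truth.
#'
#' @param truth data.frame with column `onset_s` (injected events).
#' @param detected data.frame from [detect_microsaccades()].
#' @param tol_s maximum onset discrepancy for a match (s).
#' @return list with counts `n_truth`, `n_detected`, `n_matched`, and the
#'   derived `precision` and `recall` (NA when undefined).
#' @export
match_events <- function(truth, detected, tol_s = 0.01) {
  nt <- nrow(truth); nd <- nrow(detected)
  matched <- 0L
  used <- rep(FALSE, nd)
  if (nt && nd) {
    for (on in truth$onset_s) {
      d <- abs(detected$onset_s - on)
      d[used] <- Inf
      j <- which.min(d)
      if (is.finite(d[j]) && d[j] <= tol_s) {
        used[j] <- TRUE
        matched <- matched + 1L
      }
    }
  }
  list(n_truth = nt, n_detected = nd, n_matched = matched,
       precision = if (nd) matched / nd else NA_real_,
       recall = if (nt) matched / nt else NA_real_)
}
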