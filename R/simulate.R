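#' Simulation settings for a synthetic experiment
#'
#' Defaults mirror the study design being emulated: 2 x 2 within-subject
#' conditions (Clarity x Ambiguity), 28 trials per condition per participant
#' spread over 4 blocks of 28 trials (7 per condition per block), 500 Hz
#' sampling, sentence durations uniform on 1.4-4.8 s, a 3 s pre-onset lead
#' and a 1.2 s post-offset tail.  The pupil response model is
#' `pupil(t) = tonic + drift + amplitude * s(t) + noise`, where `s` is a
#' sentence-long boxcar convolved with the two-parameter gamma-family pupil
#' impulse response (shape 10.1, t_max 0.93 s) and normalized to unit peak,
#' so `amplitude` is the evoked peak in tracker units.  Gaze is white
#' fixation noise with superposed raised-cosine ballistic microsaccades from
#' an inhomogeneous Poisson process with transient post-onset inhibition.
#' Behavioral responses are Bernoulli draws at condition accuracies.
#'
#' Response-amplitude and noise magnitudes are stand-ins (the emulated study
#' reports no pupil model or effect sizes in tracker units); they are chosen
#' to produce realistic-looking traces, not to reproduce printed values.
#'
#' @param n_participants number of participants.
#' @param n_trials_per_condition trials per condition per participant (28).
#' @param n_blocks number of blocks (trials are balanced within block).
#' @param sampling_rate Hz.
#' @param duration_range sentence-duration range (s), uniform draw.
#' @param lead_s,tail_s recorded lead before onset / tail after offset (s).
#' @param tonic_pupil tonic pupil area (a.u.).
#' @param response_amplitude_base evoked-peak amplitude common to all
#'   conditions (a.u.).
#' @param beta_clarity amplitude added for low-SNR trials (a.u.).
#' @param beta_ambiguity amplitude added for high-ambiguity trials (a.u.).
#' @param beta_interaction amplitude added for low-SNR x HA trials (a.u.).
#' @param subj_amp_sd SD of the per-participant amplitude offset (a.u.).
#' @param trial_amp_sd SD of the per-trial amplitude jitter (a.u.).
#' @param pupil_irf_shape_n,pupil_irf_tmax_s impulse-response parameters.
#' @param noise_sd per-sample Gaussian pupil noise SD (a.u.).
#' @param slow_sd scale of slow spontaneous pupil fluctuations, the SD of a
#'   random walk's end-of-trial deviation (a.u.); these dominate the trial's
#'   dispersion, as spontaneous fluctuations do in real recordings, so the
#'   MAD-based outlier rule does not clip the evoked response.
#' @param drift_sd SD of the total linear drift across a trial (a.u.).
#' @param blink_rate_hz Poisson blink rate (events/s).
#' @param blink_dur_range blink duration range (s).
#' @param artifact_rate probability that a trial contains one long eye
#'   closure (duration `artifact_dur_range`), emulating the small
#'   percentage of trials lost to the missing-data exclusion rule.
#' @param artifact_dur_range duration range of a long closure (s).
#' @param spike_rate_hz Poisson rate of isolated outlier spikes (events/s).
#' @param spike_amplitude magnitude of outlier spikes (a.u.).
#' @param gaze_noise_sd white fixational gaze noise SD (deg).
#' @param ms_base_rate_hz baseline microsaccade rate (events/s).
#' @param ms_inhibition_depth fractional rate dip after sentence onset.
#' @param ms_inhibition_t_s duration of the post-onset inhibition (s).
#' @param ms_amp_range microsaccade amplitude range (deg), uniform draw.
#' @param ms_dur_range microsaccade duration range (s), uniform draw.
#' @param accuracy named accuracy per cell (`LA_high`, `HA_high`, `LA_low`,
#'   `HA_low`).
#' @param timeout_rate probability a trial times out with no response.
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_participants = 35,
                       n_trials_per_condition = 28,
                       n_blocks = 4,
                       sampling_rate = 500,
                       duration_range = c(1.4, 4.8),
                       lead_s = 3.0,
                       tail_s = 1.2,
                       tonic_pupil = 1000,
                       response_amplitude_base = 30,
                       beta_clarity = 12,
                       beta_ambiguity = 6,
                       beta_interaction = -4,
                       subj_amp_sd = 10,
                       trial_amp_sd = 8,
                       pupil_irf_shape_n = 10.1,
                       pupil_irf_tmax_s = 0.93,
                       noise_sd = 15,
                       slow_sd = 60,
                       drift_sd = 15,
                       blink_rate_hz = 0.05,
                       blink_dur_range = c(0.1, 0.3),
                       artifact_rate = 0.015,
                       artifact_dur_range = c(2, 4),
                       spike_rate_hz = 0.2,
                       spike_amplitude = 300,
                       gaze_noise_sd = 0.005,
                       ms_base_rate_hz = 1.5,
                       ms_inhibition_depth = 0.7,
                       ms_inhibition_t_s = 0.5,
                       ms_amp_range = c(0.1, 1.0),
                       ms_dur_range = c(0.010, 0.025),
                       accuracy = c(LA_high = 0.92, HA_high = 0.93,
                                    LA_low = 0.89, HA_low = 0.83),
                       timeout_rate = 0.01,
                       seed = 1L) {
  cfg <- as.list(environment())
  problems <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(n_participants >= 1, "n_participants must be >= 1")
  chk(n_trials_per_condition %% n_blocks == 0,
      "n_trials_per_condition must be divisible by n_blocks")
  chk(duration_range[1] >= 1.4 && duration_range[2] <= 4.8 &&
        duration_range[1] <= duration_range[2],
      "duration_range must lie within [1.4, 4.8]")
  chk(all(c("LA_high", "HA_high", "LA_low", "HA_low") %in% names(accuracy)),
      "accuracy must name all four cells")
  chk(all(accuracy >= 0 & accuracy <= 1), "accuracies must lie in [0, 1]")
  chk(timeout_rate >= 0 && timeout_rate <= 1,
      "timeout_rate must lie in [0, 1]")
  chk(all(c(blink_rate_hz, spike_rate_hz, ms_base_rate_hz) >= 0),
      "event rates must be nonnegative")
  chk(ms_inhibition_depth >= 0 && ms_inhibition_depth <= 1,
      "ms_inhibition_depth must lie in [0, 1]")
  chk(noise_sd >= 0 && slow_sd >= 0 && drift_sd >= 0 && gaze_noise_sd >= 0,
      "noise SDs must be nonnegative")
  if (length(problems))
    stop("invalid sim_config: ", paste(problems, collapse = "; "),
         call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Pupil impulse response (gamma family)
#'
#' `h(t) = (t/t_max)^n * exp(-n * (t - t_max) / t_max)` for `t >= 0`,
#' normalized so `h(t_max) = 1`.
#'
#' @param t time in seconds (vector).
#' @param shape_n dimensionless shape (default 10.1).
#' @param tmax_s time-to-peak in seconds (default 0.93).
#' @return the impulse response evaluated at `t`.
#' @export
pupil_irf <- function(t, shape_n = 10.1, tmax_s = 0.93) {
  h <- numeric(length(t))
  pos <- t > 0
  h[pos] <- (t[pos] / tmax_s)^shape_n *
    exp(-shape_n * (t[pos] - tmax_s) / tmax_s)
  h
}

#' Pseudorandom condition order with run-length caps
#'
#' Permutes `n_per_cond` trials of each of the four Clarity x Ambiguity
#' cells so that no more than `max_run_ambiguity` (3) trials of the same
#' ambiguity level and no more than `max_run_clarity` (2) trials of the
#' same clarity level occur in a row.  Rejection sampling with a bounded
#' retry budget; the sampler is not claimed to be uniform over admissible
#' orders.
#'
#' @param n_per_cond trials per condition.
#' @param max_run_ambiguity,max_run_clarity run-length caps.
#' @param max_tries retry budget before failing.
#' @return data.frame with columns `clarity`, `ambiguity`.
#' @export
condition_order <- function(n_per_cond, max_run_ambiguity = 3,
                            max_run_clarity = 2, max_tries = 10000) {
  # cells 1:4 = (high,LA) (low,LA) (high,HA) (low,HA)
  cla_of <- c(1L, 2L, 1L, 2L)
  amb_of <- c(1L, 1L, 2L, 2L)
  base <- rep(1:4, each = n_per_cond)
  n <- length(base)
  for (i in seq_len(max_tries)) {
    cells <- base[sample.int(n)]
    if (max(rle(amb_of[cells])$lengths) <= max_run_ambiguity &&
        max(rle(cla_of[cells])$lengths) <= max_run_clarity) {
      return(data.frame(clarity = clarity_levels[cla_of[cells]],
                        ambiguity = ambiguity_levels[amb_of[cells]],
                        stringsAsFactors = FALSE))
    }
  }
  stop(sprintf("no admissible condition order found in %d tries", max_tries),
       call. = FALSE)
}

# inhomogeneous-Poisson microsaccade onsets by thinning
draw_ms_onsets <- function(t0, t1, cfg) {
  lam_max <- cfg$ms_base_rate_hz
  if (lam_max <= 0) return(numeric(0))
  n <- stats::rpois(1, lam_max * (t1 - t0))
  if (!n) return(numeric(0))
  cand <- sort(stats::runif(n, t0, t1))
  lam <- lam_max * ifelse(cand > 0 & cand <= cfg$ms_inhibition_t_s,
                          1 - cfg$ms_inhibition_depth, 1)
  cand[stats::runif(n) < lam / lam_max]
}

# one trial's trace + ground truth; `ci` is the cumulative integral of the
# IRF on the positive sample grid (precomputed per participant)
simulate_trial <- function(duration_s, amplitude, cfg, ci) {
  fs <- cfg$sampling_rate
  dt <- 1 / fs
  n_pre <- round(cfg$lead_s * fs)
  n_post <- round((duration_s + cfg$tail_s) * fs)
  t <- (-n_pre:n_post) * dt
  n <- length(t)
  dur_k <- round(duration_s * fs)

  # boxcar (*) IRF via difference of the IRF's cumulative integral
  kpos <- 0:n_post
  shape <- ci[kpos + 1L]
  lag <- kpos - dur_k
  shape[lag > 0] <- shape[lag > 0] - ci[lag[lag > 0] + 1L]
  peak <- max(shape)
  if (peak > 0) shape <- shape / peak
  response <- c(numeric(n_pre), amplitude * shape)

  drift_total <- stats::rnorm(1, 0, cfg$drift_sd)
  drift <- drift_total * (t - t[1]) / (t[n] - t[1])
  slow <- if (cfg$slow_sd > 0)
    cumsum(stats::rnorm(n)) * (cfg$slow_sd / sqrt(n)) else 0
  pupil <- cfg$tonic_pupil + drift + slow + response +
    stats::rnorm(n, 0, cfg$noise_sd)

  span <- t[n] - t[1]
  # blinks: Poisson-placed short intervals, plus a rare long closure
  n_blinks <- stats::rpois(1, cfg$blink_rate_hz * span)
  bs <- bd <- numeric(0)
  if (n_blinks) {
    bs <- sort(stats::runif(n_blinks, t[1], t[n]))
    bd <- stats::runif(n_blinks, cfg$blink_dur_range[1],
                       cfg$blink_dur_range[2])
  }
  if (cfg$artifact_rate > 0 && stats::runif(1) < cfg$artifact_rate) {
    bs <- c(bs, stats::runif(1, t[1], t[n] / 2))
    bd <- c(bd, stats::runif(1, cfg$artifact_dur_range[1],
                             cfg$artifact_dur_range[2]))
  }
  blinks <- matrix(numeric(0), ncol = 2)
  if (length(bs)) {
    be <- pmin(bs + bd, t[n])
    blinks <- cbind(bs, be)
    for (i in seq_along(bs))
      pupil[t >= bs[i] - 1e-12 & t <= be[i] + 1e-12] <- NaN
  }

  # isolated outlier spikes
  n_spikes <- stats::rpois(1, cfg$spike_rate_hz * span)
  spike_idx <- integer(0)
  if (n_spikes) {
    spike_idx <- sample(n, n_spikes)
    pupil[spike_idx] <- pupil[spike_idx] +
      sample(c(-1, 1), n_spikes, replace = TRUE) * cfg$spike_amplitude
  }

  # gaze: fixation noise + ballistic raised-cosine microsaccades
  gx <- stats::rnorm(n, 0, cfg$gaze_noise_sd)
  gy <- stats::rnorm(n, 0, cfg$gaze_noise_sd)
  onsets <- draw_ms_onsets(t[1], t[n] - max(cfg$ms_dur_range), cfg)
  ms_truth <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                         amplitude_deg = numeric(0), direction = numeric(0))
  if (length(onsets)) {
    amp <- stats::runif(length(onsets), cfg$ms_amp_range[1],
                        cfg$ms_amp_range[2])
    dur <- stats::runif(length(onsets), cfg$ms_dur_range[1],
                        cfg$ms_dur_range[2])
    theta <- stats::runif(length(onsets), 0, 2 * pi)
    for (k in seq_along(onsets)) {
      after <- t >= onsets[k]
      u <- pmin((t[after] - onsets[k]) / dur[k], 1)
      # displacement of a raised-cosine velocity profile, total = amp
      disp <- amp[k] * (u - sin(2 * pi * u) / (2 * pi))
      gx[after] <- gx[after] + cos(theta[k]) * disp
      gy[after] <- gy[after] + sin(theta[k]) * disp
    }
    ms_truth <- data.frame(onset_s = onsets, duration_s = dur,
                           amplitude_deg = amp, direction = theta)
  }

  list(trace = sample_trace(t, pupil, gx, gy, blink_intervals = blinks,
                            sampling_rate = fs),
       truth = list(amplitude = amplitude, blink_intervals = blinks,
                    spike_idx = spike_idx, microsaccades = ms_truth))
}

#' Simulate a complete synthetic experiment
#'
#' Generates trial metadata, eye-tracker traces and ground truth for
#' `cfg$n_participants` participants under the 2 x 2 design, with
#' block-wise pseudorandom condition orders obeying the run-length caps.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param experiment experiment label stored in the trial table (1 or 2).
#' @return list with `trials` (data.frame), `traces` (list of
#'   [sample_trace()], one per trial row) and `truth` (list of per-trial
#'   ground truth: injected amplitude, blink intervals, spike indices,
#'   microsaccade events, correctness indicator).
#' @export
simulate_experiment <- function(cfg = sim_config(), experiment = 1L) {
  set.seed(cfg$seed)
  per_block <- cfg$n_trials_per_condition / cfg$n_blocks
  betas <- c(LA_high = 0,
             HA_high = cfg$beta_ambiguity,
             LA_low = cfg$beta_clarity,
             HA_low = cfg$beta_clarity + cfg$beta_ambiguity +
               cfg$beta_interaction)

  fs <- cfg$sampling_rate
  max_post <- round((cfg$duration_range[2] + cfg$tail_s) * fs)
  tp <- (0:max_post) / fs
  ci <- cumsum(pupil_irf(tp, cfg$pupil_irf_shape_n, cfg$pupil_irf_tmax_s)) / fs

  n_total <- cfg$n_participants * cfg$n_blocks * 4L * per_block
  participant_id <- character(n_total); block <- integer(n_total)
  trial <- integer(n_total); clarity <- character(n_total)
  ambiguity <- character(n_total); dur_v <- numeric(n_total)
  probe_v <- logical(n_total); resp_v <- character(n_total)
  rt_v <- numeric(n_total)
  traces <- vector("list", n_total)
  truth <- vector("list", n_total)
  row <- 0L
  for (p in seq_len(cfg$n_participants)) {
    pid <- sprintf("P%03d", p)
    subj_amp <- stats::rnorm(1, 0, cfg$subj_amp_sd)
    for (b in seq_len(cfg$n_blocks)) {
      ord <- condition_order(per_block)
      for (i in seq_len(nrow(ord))) {
        row <- row + 1L
        cell <- cell_label(ord$clarity[i], ord$ambiguity[i])
        dur <- stats::runif(1, cfg$duration_range[1], cfg$duration_range[2])
        amp <- cfg$response_amplitude_base + betas[[cell]] + subj_amp +
          stats::rnorm(1, 0, cfg$trial_amp_sd)
        sim <- simulate_trial(dur, amp, cfg, ci)

        correct <- stats::runif(1) < cfg$accuracy[[cell]]
        timeout <- stats::runif(1) < cfg$timeout_rate
        probe_related <- stats::runif(1) < 0.5
        participant_id[row] <- pid; block[row] <- b; trial[row] <- i
        clarity[row] <- ord$clarity[i]; ambiguity[row] <- ord$ambiguity[i]
        dur_v[row] <- dur; probe_v[row] <- probe_related
        resp_v[row] <- if (timeout) "none" else
          if (correct == probe_related) "related" else "unrelated"
        rt_v[row] <- if (timeout) NA_real_ else stats::runif(1, 0.6, 3.4)
        traces[[row]] <- sim$trace
        sim$truth$correct <- correct && !timeout
        truth[[row]] <- sim$truth
      }
    }
  }
  trials <- data.frame(
    participant_id = participant_id, experiment = experiment, block = block,
    trial = trial, clarity = clarity, ambiguity = ambiguity,
    sentence_onset_s = 0, sentence_duration_s = dur_v,
    probe_related = probe_v, response = resp_v, response_time_s = rt_v,
    trial_key = sprintf("%s_%d_%d", participant_id, block, trial),
    stringsAsFactors = FALSE)
  list(trials = trials, traces = traces, truth = truth)
}
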