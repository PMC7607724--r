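# Vectorized (matrix) implementation of the single-trial pupil chain, used
# for simulation sweeps where thousands of trials share one time grid.  The
# arithmetic is identical to preprocess_trial()/trial_metrics(); the
# equivalence is asserted in the test suite.

#' Preprocess a batch of equal-grid trials
#'
#' Runs the canonical chain (blink masking, MAD outlier masking, linear
#' interpolation, exclusion decision, Kaiser FIR low-pass, baseline
#' correction) and extracts the pupil metrics for a matrix of trials that
#' share one time grid and sentence duration.  Produces exactly the numbers
#' [preprocess_trial()] + [trial_metrics()] produce trial by trial.
#'
#' @param P numeric matrix, samples x trials, of raw pupil values (`NaN`
#'   where the device lost the pupil).
#' @param t shared time grid (s, onset-relative).
#' @param sampling_rate sampling rate (Hz).
#' @param sentence_duration_s shared sentence duration (s).
#' @param blinks list (length = trials) of two-column blink-interval
#'   matrices; `NULL` entries mean no blinks.
#' @param cfg a [pipeline_config()].
#' @return list of per-trial vectors: `mean_dilation`, `peak_dilation`,
#'   `peak_latency_s`, `nan_fraction`, `excluded`.
#' @export
preprocess_matrix <- function(P, t, sampling_rate, sentence_duration_s,
                              blinks = NULL, cfg = pipeline_config()) {
  n <- nrow(P); m <- ncol(P)
  # blink masking with the (-blink_pre_s, +blink_post_s) expansion
  if (!is.null(blinks)) {
    for (j in seq_len(m)) {
      bl <- blinks[[j]]
      if (is.null(bl) || !nrow(bl)) next
      for (i in seq_len(nrow(bl))) {
        lo <- bl[i, 1] - cfg$blink_pre_s
        hi <- bl[i, 2] + cfg$blink_post_s
        P[t >= lo - 1e-12 & t <= hi + 1e-12, j] <- NaN
      }
    }
  }
  # per-trial median/MAD outlier masking
  for (j in seq_len(m)) {
    x <- P[, j]
    fin <- is.finite(x)
    if (sum(fin) < 2) next  # exclusion is forced below
    med <- fast_median(x[fin])
    mad_raw <- fast_median(abs(x[fin] - med))
    x[fin & abs(x - med) > cfg$mad_k * mad_raw] <- NaN
    P[, j] <- x
  }
  # exclusion on the pre-interpolation mask
  lo <- -cfg$exclusion_pre_s
  hi <- sentence_duration_s + cfg$exclusion_post_s
  inwin <- t >= lo - 1e-12 & t <= hi + 1e-12
  nan_fraction <- colMeans(!is.finite(P[inwin, , drop = FALSE]))
  excluded <- nan_fraction > cfg$nan_frac_max
  keep <- which(!excluded)
  # interpolation (interior linear, edges constant)
  for (j in keep) P[, j] <- na_interp(t, P[, j])
  # zero-phase FIR with reflection padding, whole batch at once; the
  # centred convolution is applied as a banded-matrix multiply (the taps
  # are symmetric, so orientation is immaterial)
  h <- kaiser_lowpass_taps(sampling_rate, cfg)
  half <- (cfg$fir_length - 1L) %/% 2L
  L <- cfg$fir_length
  Pk <- P[, keep, drop = FALSE]
  padded <- rbind(Pk[(half + 1):2, , drop = FALSE], Pk,
                  Pk[(n - 1):(n - half), , drop = FALSE])
  H <- matrix(0, n, n + 2L * half)
  H[cbind(rep(seq_len(n), each = L),
          rep(seq_len(n), each = L) + rep(0:(L - 1L), n))] <- h
  Y <- H %*% padded
  # baseline correction (closed-open window)
  bwin <- t >= cfg$baseline_window[1] - 1e-12 &
    t < cfg$baseline_window[2] - 1e-12
  Y <- sweep(Y, 2, colMeans(Y[bwin, , drop = FALSE]))
  # metrics over the sentence-locked window
  w <- metric_window(sentence_duration_s, cfg)
  mwin <- t >= w[1] - 1e-12 & t <= w[2] + 1e-12
  Yw <- Y[mwin, , drop = FALSE]
  tw <- t[mwin]
  mean_dil <- peak_dil <- peak_lat <- rep(NA_real_, m)
  if (length(keep)) {
    mean_dil[keep] <- colMeans(Yw)
    imax <- apply(Yw, 2, which.max)
    peak_dil[keep] <- Yw[cbind(imax, seq_along(keep))]
    peak_lat[keep] <- tw[imax]
  }
  list(mean_dilation = mean_dil, peak_dilation = peak_dil,
       peak_latency_s = peak_lat, nan_fraction = nan_fraction,
       excluded = excluded)
}

# batch-simulate one participant's pupil matrix (shared duration grid);
# same generative model as simulate_trial(), vectorized over trials
simulate_participant_matrix <- function(t, n_pre, shape, cells, amps, cfg) {
  n <- length(t)
  m <- length(cells)
  response <- outer(c(numeric(n_pre), shape), amps)
  drift <- outer((t - t[1]) / (t[n] - t[1]),
                 stats::rnorm(m, 0, cfg$drift_sd))
  noise <- matrix(stats::rnorm(n * m, 0, cfg$noise_sd), n, m)
  P <- cfg$tonic_pupil + response + drift + noise
  if (cfg$slow_sd > 0) {
    W <- matrix(stats::rnorm(n * m), n, m)
    W <- apply(W, 2, cumsum) * (cfg$slow_sd / sqrt(n))
    P <- P + W
  }
  span <- t[n] - t[1]
  blinks <- vector("list", m)
  n_bl <- stats::rpois(m, cfg$blink_rate_hz * span)
  long <- cfg$artifact_rate > 0 &
    stats::runif(m) < cfg$artifact_rate
  for (j in which(n_bl > 0 | long)) {
    k <- n_bl[j]
    bs <- if (k) sort(stats::runif(k, t[1], t[n])) else numeric(0)
    bd <- if (k) stats::runif(k, cfg$blink_dur_range[1],
                              cfg$blink_dur_range[2]) else numeric(0)
    if (long[j]) {
      bs <- c(bs, stats::runif(1, t[1], t[n] / 2))
      bd <- c(bd, stats::runif(1, cfg$artifact_dur_range[1],
                               cfg$artifact_dur_range[2]))
    }
    be <- pmin(bs + bd, t[n])
    blinks[[j]] <- cbind(bs, be)
    for (i in seq_along(bs))
      P[t >= bs[i] - 1e-12 & t <= be[i] + 1e-12, j] <- NaN
  }
  n_sp <- stats::rpois(m, cfg$spike_rate_hz * span)
  for (j in which(n_sp > 0)) {
    idx <- sample.int(n, n_sp[j])
    P[idx, j] <- P[idx, j] +
      sample(c(-1, 1), n_sp[j], replace = TRUE) * cfg$spike_amplitude
  }
  list(P = P, blinks = blinks)
}

#' Simulate one experiment on a shared grid and return its condition table
#'
#' Batch counterpart of [simulate_experiment()] + [analyze_cohort()] for
#' simulation sweeps: every trial uses the common sentence duration
#' `sim_cfg$duration_range[1]` so one time grid is shared, the cohort is
#' generated with the same pupil model, and the full preprocessing chain
#' runs through [preprocess_matrix()].  Consumes the ambient RNG stream
#' (callers seed once per sweep).
#'
#' @param sim_cfg a [sim_config()].
#' @param cfg a [pipeline_config()].
#' @param measure `"mean_dilation"`, `"peak_dilation"` or `"peak_latency_s"`.
#' @return a condition table (as from [build_condition_table()]).
#' @export
matrix_experiment_table <- function(sim_cfg = sim_config(),
                                    cfg = pipeline_config(),
                                    measure = "mean_dilation") {
  scfg <- sim_cfg
  fs <- scfg$sampling_rate
  dur <- scfg$duration_range[1]
  n_pre <- round(scfg$lead_s * fs)
  n_post <- round((dur + scfg$tail_s) * fs)
  t <- (-n_pre:n_post) / fs
  tp <- (0:n_post) / fs
  ci <- cumsum(pupil_irf(tp, scfg$pupil_irf_shape_n,
                         scfg$pupil_irf_tmax_s)) / fs
  dur_k <- round(dur * fs)
  shape <- ci
  lag <- (0:n_post) - dur_k
  shape[lag > 0] <- shape[lag > 0] - ci[lag[lag > 0] + 1L]
  shape <- shape / max(shape)

  betas <- c(LA_high = 0,
             HA_high = scfg$beta_ambiguity,
             LA_low = scfg$beta_clarity,
             HA_low = scfg$beta_clarity + scfg$beta_ambiguity +
               scfg$beta_interaction)
  m <- scfg$n_trials_per_condition * 4L
  cells <- rep(condition_cells, each = scfg$n_trials_per_condition)
  vals <- matrix(NA_real_, nrow = scfg$n_participants, ncol = 4,
                 dimnames = list(NULL, condition_cells))
  for (p in seq_len(scfg$n_participants)) {
    subj_amp <- stats::rnorm(1, 0, scfg$subj_amp_sd)
    amps <- scfg$response_amplitude_base + betas[cells] + subj_amp +
      stats::rnorm(m, 0, scfg$trial_amp_sd)
    sim <- simulate_participant_matrix(t, n_pre, shape, cells, amps, scfg)
    pp <- preprocess_matrix(sim$P, t, fs, dur, sim$blinks, cfg)
    v <- pp[[measure]]
    for (cl in condition_cells)
      vals[p, cl] <- mean(v[cells == cl & !pp$excluded])
  }
  tab <- data.frame(participant = sprintf("P%03d", seq_len(nrow(vals))),
                    vals, check.names = FALSE, stringsAsFactors = FALSE)
  attr(tab, "measure") <- measure
  tab
}

#' Empirical type-I error of the 2 x 2 rmANOVA over simulated null cohorts
#'
#' Simulates `n_reps` complete experiments under the null (all condition
#' betas forced to 0), runs the full pupil preprocessing chain and the
#' rmANOVA on each, and reports the fraction of replicates in which each
#' effect rejects at `alpha`.  Uses [matrix_experiment_table()], whose
#' trial chain is arithmetic-identical to the per-trial functions, so large
#' sweeps are feasible.
#'
#' @param sim_cfg a [sim_config()]; betas are overridden to 0 and the first
#'   element of `duration_range` is used as the common sentence duration.
#' @param cfg a [pipeline_config()].
#' @param n_reps number of replicate experiments.
#' @param alpha nominal level.
#' @param measure which metric's rmANOVA to monitor.
#' @return list with `rejection_rate` (named, one entry per effect),
#'   `n_reps` and `alpha`.
#' @export
calibrate_type1_error <- function(sim_cfg = sim_config(),
                                  cfg = pipeline_config(),
                                  n_reps = 500, alpha = 0.05,
                                  measure = "mean_dilation") {
  scfg <- sim_cfg
  scfg$beta_clarity <- 0; scfg$beta_ambiguity <- 0; scfg$beta_interaction <- 0
  set.seed(scfg$seed)
  rej <- matrix(0L, nrow = n_reps, ncol = 3)
  for (r in seq_len(n_reps)) {
    a <- rmanova_2x2(matrix_experiment_table(scfg, cfg, measure))
    rej[r, ] <- as.integer(a$p < alpha)
  }
  rates <- colMeans(rej)
  names(rates) <- c("Clarity", "Ambiguity", "Clarity:Ambiguity")
  list(rejection_rate = rates, n_reps = n_reps, alpha = alpha)
}

#' Recovery of injected condition effects over simulated cohorts
#'
#' Simulates `n_reps` experiments with the configured (nonzero) Clarity and
#' Ambiguity amplitudes, runs the preprocessing chain and rmANOVA, and
#' reports how often each main effect is recovered with the correct
#' (positive) sign at `alpha`.
#'
#' @inheritParams calibrate_type1_error
#' @return list with `recovery_rate` (named: Clarity, Ambiguity), `n_reps`
#'   and `alpha`.
#' @export
recover_effects <- function(sim_cfg = sim_config(), cfg = pipeline_config(),
                            n_reps = 100, alpha = 0.05,
                            measure = "mean_dilation") {
  set.seed(sim_cfg$seed)
  hit <- matrix(0L, nrow = n_reps, ncol = 2)
  for (r in seq_len(n_reps)) {
    tab <- matrix_experiment_table(sim_cfg, cfg, measure)
    m <- as.matrix(tab[condition_cells])
    d <- within_contrasts(m)
    a <- rmanova_2x2(tab)
    hit[r, 1] <- as.integer(a$p[1] < alpha && mean(d$Clarity) > 0)
    hit[r, 2] <- as.integer(a$p[2] < alpha && mean(d$Ambiguity) > 0)
  }
  rates <- colMeans(hit)
  names(rates) <- c("Clarity", "Ambiguity")
  list(recovery_rate = rates, n_reps = n_reps, alpha = alpha)
}
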