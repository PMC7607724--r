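#' Mono waveform container
#'
#' @param samples numeric amplitude sequence (nominal full scale +/- 1).
#' @param sampling_rate sampling rate in Hz.
#' @return an object of class `waveform`.
#' @export
waveform <- function(samples, sampling_rate) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples)))
    stop("waveform samples must be finite", call. = FALSE)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive", call. = FALSE)
  structure(list(samples = samples, sampling_rate = sampling_rate),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s), RMS %.4g\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, rms(x$samples)))
  invisible(x)
}

#' Root-mean-square amplitude
#' @param x numeric vector or `waveform`.
#' @return the RMS value.
#' @export
rms <- function(x) {
  if (inherits(x, "waveform")) x <- x$samples
  sqrt(mean(x^2))
}

#' Masker construction settings
#'
#' Defaults follow the stimulus timing used throughout: a 3 s masker-only
#' lead before sentence onset, a 1.2 s tail after offset, 10 ms linear on/off
#' ramps, a 30 Hz Butterworth envelope low-pass and 30 babble streams.
#'
#' @param snr_db target signal-to-noise ratio in dB (study levels: +6, 0, -2).
#' @param env_lp_cutoff_hz envelope low-pass cutoff (Hz).
#' @param env_lp_order Butterworth order (applied forward-backward).
#' @param lead_s,tail_s masker-only lead/tail around the sentence (s).
#' @param ramp_s linear fade duration (s).
#' @param babble_n number of independent babble streams averaged.
#' @return a `masking_config` list.
#' @export
masking_config <- function(snr_db = 0, env_lp_cutoff_hz = 30,
                           env_lp_order = 4, lead_s = 3.0, tail_s = 1.2,
                           ramp_s = 0.01, babble_n = 30) {
  if (ramp_s >= lead_s || ramp_s >= tail_s)
    stop("ramp_s must be shorter than lead_s and tail_s", call. = FALSE)
  structure(list(snr_db = snr_db, env_lp_cutoff_hz = env_lp_cutoff_hz,
                 env_lp_order = env_lp_order, lead_s = lead_s,
                 tail_s = tail_s, ramp_s = ramp_s, babble_n = babble_n),
            class = "masking_config")
}

# Analytic signal by the standard FFT construction: zero negative
# frequencies, double positive ones, keep DC (and Nyquist for even n).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Amplitude envelope of a waveform
#'
#' Magnitude of the analytic (Hilbert) signal, low-pass filtered with a
#' zero-phase Butterworth at `cfg$env_lp_cutoff_hz`; filter-induced
#' negative excursions are clipped to zero.
#'
#' @param w a [waveform()].
#' @param cfg a [masking_config()].
#' @return nonnegative numeric vector, same length as `w$samples`.
#' @export
amplitude_envelope <- function(w, cfg = masking_config()) {
  if (w$sampling_rate <= 2 * cfg$env_lp_cutoff_hz)
    stop(sprintf("sampling rate %g Hz too low for a %g Hz envelope filter",
                 w$sampling_rate, cfg$env_lp_cutoff_hz), call. = FALSE)
  x <- w$samples
  n <- length(x)
  # reflect ~100 ms at each end so the FFT wrap-around and the filter
  # transient fall in the padding, not in the returned envelope
  npad <- min(n - 1, round(0.1 * w$sampling_rate))
  xp <- c(rev(x[seq_len(npad) + 1L]), x, rev(x[(n - npad):(n - 1L)]))
  env <- Mod(analytic_signal(xp))
  bf <- signal::butter(cfg$env_lp_order,
                       cfg$env_lp_cutoff_hz / (w$sampling_rate / 2),
                       type = "low")
  env <- signal::filtfilt(bf, env)
  pmax(env[(npad + 1):(npad + n)], 0)
}

#' Pink (1/f) noise
#'
#' Spectral-synthesis pink noise: unit-variance white Gaussian spectrum
#' shaped by `1/sqrt(f)` amplitude (power spectral density proportional to
#' `1/f`, i.e. -10 dB/decade), then scaled to unit RMS.
#'
#' @param n number of samples.
#' @param sampling_rate sampling rate in Hz.
#' @return a [waveform()] with unit RMS.
#' @export
pink_noise <- function(n, sampling_rate) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  nfreq <- floor(n / 2)
  f <- seq_len(nfreq) * sampling_rate / n
  amp <- 1 / sqrt(f)
  phase <- stats::runif(nfreq, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  X <- complex(real = numeric(n))
  X[2:(nfreq + 1)] <- spec
  # hermitian symmetry for a real signal
  idx <- if (n %% 2 == 0) 2:nfreq else 2:(nfreq + 1)
  X[n + 2 - idx] <- Conj(X[idx])
  if (n %% 2 == 0) X[nfreq + 1] <- complex(real = amp[nfreq] *
                                             sign(stats::rnorm(1)))
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  waveform(x / rms(x), sampling_rate)
}

#' Envelope-modulated pink-noise masker
#'
#' Builds the masker used for acoustically degrading a sentence while
#' keeping the masking level constant over its course: pink noise of equal
#' length, multiplied samplewise by the target's 30 Hz low-passed Hilbert
#' amplitude envelope.  Deterministic given `seed`.
#'
#' @param target target sentence [waveform()].
#' @param cfg a [masking_config()].
#' @param seed integer RNG seed.
#' @return a [waveform()] of equal length.
#' @export
make_env_pink_masker <- function(target, cfg = masking_config(), seed = NULL) {
  if (!length(target$samples)) stop("target is empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  env <- amplitude_envelope(target, cfg)
  pn <- pink_noise(length(target$samples), target$sampling_rate)
  waveform(pn$samples * env, target$sampling_rate)
}

#' Mix a target and masker at an exact SNR
#'
#' SNR is defined as `20*log10(rms(target)/rms(masker))` over the common
#' span.  The designated component is rescaled so the mixture attains
#' `snr_db` exactly; the other is left untouched.
#'
#' @param target,masker equal-length, equal-rate [waveform()]s.
#' @param snr_db requested SNR in dB.
#' @param mode which component to rescale.
#' @return a list with `mix`, `target`, `masker` (post-scaling) and `gain`.
#' @export
mix_at_snr <- function(target, masker, snr_db,
                       mode = c("scale_target", "scale_masker")) {
  mode <- match.arg(mode)
  if (length(target$samples) != length(masker$samples))
    stop("target and masker must have equal length", call. = FALSE)
  if (target$sampling_rate != masker$sampling_rate)
    stop("target and masker must share a sampling rate", call. = FALSE)
  rt <- rms(target); rm_ <- rms(masker)
  if (rm_ == 0) stop("masker has zero RMS", call. = FALSE)
  if (rt == 0 && mode == "scale_masker")
    stop("target has zero RMS; SNR undefined", call. = FALSE)
  current <- 20 * log10(rt / rm_)
  gain <- 10^((snr_db - current) / 20)
  if (mode == "scale_target") {
    target <- waveform(target$samples * gain, target$sampling_rate)
  } else {
    masker <- waveform(masker$samples / gain, masker$sampling_rate)
  }
  list(mix = waveform(target$samples + masker$samples, target$sampling_rate),
       target = target, masker = masker, gain = gain)
}

#' Multi-talker babble from a sentence set
#'
#' Concatenates the sentence set `n_streams` times in independent random
#' orders, truncates every stream to the shortest concatenation and averages
#' samplewise.  The result inherits the long-term spectrum of the materials
#' with a flattened envelope.  Deterministic given `seed`.
#'
#' @param sentences list of [waveform()]s at a common sampling rate.
#' @param n_streams number of streams averaged.
#' @param seed integer RNG seed.
#' @return a [waveform()].
#' @export
make_babble <- function(sentences, n_streams = 30, seed = NULL) {
  if (!length(sentences)) stop("need at least one sentence", call. = FALSE)
  rates <- vapply(sentences, function(w) w$sampling_rate, numeric(1))
  if (length(unique(rates)) != 1)
    stop("sentences have mixed sampling rates", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  streams <- lapply(seq_len(n_streams), function(i) {
    ord <- sample(length(sentences))
    unlist(lapply(sentences[ord], function(w) w$samples), use.names = FALSE)
  })
  len <- min(lengths(streams))
  acc <- numeric(len)
  for (s in streams) acc <- acc + s[seq_len(len)]
  waveform(acc / n_streams, rates[1])
}

#' Frame a mixture with leading and trailing masker
#'
#' Surrounds the sentence mixture with a masker-only lead of `cfg$lead_s`
#' and tail of `cfg$tail_s`, applying linear on/off ramps of `cfg$ramp_s` to
#' the masker.  Sample counts: `round(lead_s*fs) + length(mix) +
#' round(tail_s*fs)` exactly.
#'
#' @param mix the sentence (or sentence+masker) [waveform()].
#' @param masker masker [waveform()] at least `lead + mix + tail` long.
#' @param cfg a [masking_config()].
#' @return a [waveform()] of the framed stimulus.
#' @export
frame_with_noise <- function(mix, masker, cfg = masking_config()) {
  fs <- mix$sampling_rate
  if (masker$sampling_rate != fs)
    stop("mix and masker must share a sampling rate", call. = FALSE)
  n_lead <- round(cfg$lead_s * fs)
  n_tail <- round(cfg$tail_s * fs)
  n_mix <- length(mix$samples)
  n_total <- n_lead + n_mix + n_tail
  if (length(masker$samples) < n_total)
    stop(sprintf("masker too short: need %d samples, have %d",
                 n_total, length(masker$samples)), call. = FALSE)
  m <- masker$samples[seq_len(n_total)]
  n_ramp <- round(cfg$ramp_s * fs)
  if (n_ramp > 0) {
    ramp <- seq(0, 1, length.out = n_ramp)
    m[seq_len(n_ramp)] <- m[seq_len(n_ramp)] * ramp
    m[(n_total - n_ramp + 1):n_total] <-
      m[(n_total - n_ramp + 1):n_total] * rev(ramp)
  }
  out <- m
  out[(n_lead + 1):(n_lead + n_mix)] <-
    out[(n_lead + 1):(n_lead + n_mix)] + mix$samples
  waveform(out, fs)
}

#' Normalize a waveform to a target RMS
#'
#' @param w a [waveform()].
#' @param target_rms desired RMS (> 0).
#' @return the rescaled [waveform()].
#' @export
rms_normalize <- function(w, target_rms) {
  r <- rms(w)
  if (r == 0) stop("cannot RMS-normalize a silent waveform", call. = FALSE)
  if (target_rms <= 0) stop("target_rms must be positive", call. = FALSE)
  waveform(w$samples * (target_rms / r), w$sampling_rate)
}
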