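cfg <- pipeline_config()

test_that("blink masking blanks the padded closed interval on the grid", {
  tr <- make_trace(lead = 1, t_end = 4, blinks = rbind(c(2.00, 2.10)))
  out <- mask_blinks(tr, cfg)
  nan_idx <- which(is.nan(out$pupil))
  expect_identical(length(nan_idx), 176L)  # [1.95, 2.30] on the 2 ms grid
  expect_equal(out$t[min(nan_idx)], 1.95, tolerance = 1e-9)
  expect_equal(out$t[max(nan_idx)], 2.30, tolerance = 1e-9)
  expect_identical(out$gaze_x, tr$gaze_x)

  expect_identical(mask_blinks(make_trace(), cfg)$pupil, make_trace()$pupil)
})

test_that("overlapping expanded blink windows merge into one NaN span", {
  tr <- make_trace(lead = 1, t_end = 4,
                   blinks = rbind(c(1.0, 1.1), c(1.35, 1.45)))
  out <- mask_blinks(tr, cfg)
  r <- rle(is.nan(out$pupil))
  expect_identical(sum(r$values), 1L)  # windows [0.95,1.30] and [1.30,1.65]
})

test_that("MAD outlier rule masks only genuine outliers, strictly", {
  tr <- make_trace(lead = 0, t_end = 0.008,
                   pupil = function(t) c(1, 2, 3, 4, 100))
  out <- mask_outliers(tr, cfg)  # median 3, MAD 1 -> only 100 exceeds 3
  expect_identical(which(is.nan(out$pupil)), 5L)

  const <- make_trace(pupil = function(t) rep(7, length(t)))
  expect_identical(mask_outliers(const, cfg)$pupil, const$pupil)

  allnan <- make_trace(pupil = function(t) rep(NaN, length(t)))
  expect_error(mask_outliers(allnan, cfg), "missing")
})

test_that("outlier statistics are computed after blink masking", {
  # garbage covering most of a blink would dominate the median if blink
  # samples were not masked first; after masking, the inliers survive
  tr <- make_trace(lead = 0, t_end = 2,
                   pupil = function(t) ifelse(t > 0.2 & t < 1.5, 1e5, 10),
                   blinks = rbind(c(0.2, 1.5)))
  raw_med <- median(tr$pupil)
  expect_gt(raw_med, 10)  # unmasked statistics would be ruined
  out <- mask_outliers(mask_blinks(tr, cfg), cfg)
  expect_true(all(is.finite(out$pupil[out$t < 0.1 | out$t > 1.8])))
})

test_that("gap interpolation is linear inside, constant at the edges", {
  tr <- make_trace(lead = 0, t_end = 0.004,
                   pupil = function(t) c(1, NaN, 3))
  expect_equal(interpolate_gaps(tr)$pupil, c(1, 2, 3))

  tr2 <- make_trace(lead = 0, t_end = 0.006,
                    pupil = function(t) c(NaN, NaN, 5, 7))
  expect_equal(interpolate_gaps(tr2)$pupil, c(5, 5, 5, 7))

  tr3 <- make_trace(pupil = function(t) seq_along(t) + 0)
  expect_identical(interpolate_gaps(tr3)$pupil, tr3$pupil)

  tr4 <- make_trace(lead = 0, t_end = 0.004,
                    pupil = function(t) c(NaN, 2, NaN))
  expect_error(interpolate_gaps(tr4), "finite")
})

test_that("exclusion rule is strict at 40% and windowed", {
  dur <- 1.5
  tr <- make_trace(lead = 3, t_end = dur + 1.2)
  win <- tr$t >= -0.5 & tr$t <= dur + 1.0
  n_win <- sum(win)
  idx_win <- which(win)

  k40 <- round(0.40 * n_win)
  tr40 <- tr; tr40$pupil[idx_win[seq_len(k40)]] <- NaN
  dec <- exclusion_decision(tr40, dur, cfg)
  expect_equal(dec$nan_fraction, k40 / n_win, tolerance = 1e-12)
  expect_false(dec$excluded)

  tr41 <- tr; tr41$pupil[idx_win[seq_len(k40 + 1)]] <- NaN
  expect_true(exclusion_decision(tr41, dur, cfg)$excluded)

  # NaN entirely outside the window never excludes
  trout <- tr; trout$pupil[tr$t < -0.5 | tr$t > dur + 1.0] <- NaN
  expect_false(exclusion_decision(trout, dur, cfg)$excluded)

  expect_error(exclusion_decision(make_trace(lead = 0.2, t_end = 1), dur, cfg),
               "window")
})

test_that("Kaiser FIR low-pass has unit DC gain and the designed band edges", {
  const <- make_trace(lead = 2, t_end = 4, pupil = function(t) rep(3.7, length(t)))
  out <- lowpass_10hz(const, cfg)
  expect_lt(max(abs(out$pupil - 3.7)), 1e-9)

  gain_at <- function(f) {
    tr <- make_trace(lead = 2, t_end = 6,
                     pupil = function(t) sin(2 * pi * f * t))
    y <- lowpass_10hz(tr, cfg)$pupil
    mid <- tr$t > -1 & tr$t < 5
    sqrt(mean(y[mid]^2)) / sqrt(mean(sin(2 * pi * f * tr$t[mid])^2))
  }
  expect_lt(abs(gain_at(2) - 1), 0.01)
  expect_lt(gain_at(50), 0.01)

  short <- make_trace(lead = 0, t_end = 0.2)
  expect_error(lowpass_10hz(short, cfg), "filter")
})

test_that("filtering is zero net phase (time-aligned output)", {
  tr <- make_trace(lead = 2, t_end = 6,
                   pupil = function(t) sin(2 * pi * 2 * t))
  y <- lowpass_10hz(tr, cfg)$pupil
  mid <- which(tr$t > -1 & tr$t < 5)
  lags <- -10:10
  xc <- vapply(lags, function(L)
    cor(y[mid], sin(2 * pi * 2 * tr$t[mid + L])), numeric(1))
  expect_identical(lags[which.max(xc)], 0L)
})

test_that("baseline correction zeroes the baseline window and is idempotent", {
  tr <- make_trace(pupil = function(t) rep(12, length(t)))
  bc <- baseline_correct(tr, cfg)
  expect_equal(bc$baseline_mean, 12)
  expect_lt(max(abs(bc$trace$pupil)), 1e-9)

  tr2 <- make_trace(pupil = function(t) 10 + 5 * pmax(0, pmin(t, 1)))
  bc2 <- baseline_correct(tr2, cfg)
  expect_equal(max(bc2$trace$pupil), 5, tolerance = 1e-9)
  bc3 <- baseline_correct(bc2$trace, cfg)
  expect_lt(abs(bc3$baseline_mean), 1e-9)
})

test_that("preprocess_trial composes the stages and skips metrics when excluded", {
  clean_tr <- make_trace(lead = 3, t_end = 2.7,
                         pupil = function(t) 10 + sin(2 * pi * 0.5 * t))
  res <- preprocess_trial(clean_tr, 1.5, cfg)
  expect_false(res$excluded)
  expect_equal(res$nan_fraction, 0)
  bwin <- res$trace$t >= -0.5 & res$trace$t < 0
  expect_lt(abs(mean(res$trace$pupil[bwin])), 1e-9)

  half_blink <- make_trace(lead = 3, t_end = 2.7,
                           blinks = rbind(c(-0.5, 1.2)))
  res2 <- preprocess_trial(half_blink, 1.5, cfg)
  expect_true(res2$excluded)
  expect_identical(res2$exclusion_reason, "nan_fraction")
})

test_that("an injected response survives preprocessing with its amplitude", {
  sc <- sim_config(n_participants = 1, seed = 12, noise_sd = 1, slow_sd = 0,
                   drift_sd = 0, trial_amp_sd = 0, subj_amp_sd = 0,
                   blink_rate_hz = 0, spike_rate_hz = 0, artifact_rate = 0,
                   ms_base_rate_hz = 0, timeout_rate = 0)
  sim <- simulate_experiment(sc)
  i <- 1
  # near-noise-free fixture: MAD reflects only noise_sd, so widen the
  # outlier rule to keep it from clipping the (deliberately large) response
  cfgw <- pipeline_config(mad_k = 1e6)
  clean <- preprocess_trial(sim$traces[[i]], sim$trials$sentence_duration_s[i], cfgw)
  tm <- trial_metrics(clean, sim$trials$sentence_duration_s[i], cfgw)
  expect_lt(abs(tm$peak_dilation - sim$truth[[i]]$amplitude) /
              sim$truth[[i]]$amplitude, 0.05)
})

test_that("excluded-trial percentage rises with blink load", {
  cfg2 <- pipeline_config(fir_length = 101)
  pct <- vapply(c(0, 0.5, 2.5), function(rate) {
    sc <- sim_config(n_participants = 1, seed = 99, blink_rate_hz = rate,
                     artifact_rate = 0, ms_base_rate_hz = 0,
                     duration_range = c(1.5, 1.5), sampling_rate = 100)
    sim <- simulate_experiment(sc)
    excl <- vapply(seq_along(sim$traces), function(i)
      preprocess_trial(sim$traces[[i]], 1.5, cfg2)$excluded, logical(1))
    100 * mean(excl)
  }, numeric(1))
  expect_true(all(diff(pct) >= 0))
  expect_equal(pct[1], 0)
  expect_gt(pct[3], 0)
})
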