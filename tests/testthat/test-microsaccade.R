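cfg <- pipeline_config()

test_that("the 5-point velocity stencil is exact for low-order polynomials", {
  fs <- 500
  ramp <- make_trace(lead = 0, t_end = 1, fs = fs,
                     gaze_x = function(t) 3 * t,         # 3 deg/s
                     gaze_y = function(t) -1.5 * t)
  v <- gaze_velocity(ramp)
  i <- 3:(length(ramp$t) - 2)
  expect_equal(v$vx[i], rep(3, length(i)), tolerance = 1e-9)
  expect_equal(v$vy[i], rep(-1.5, length(i)), tolerance = 1e-9)
  expect_true(all(is.na(v$vx[c(1, 2)])))

  const <- make_trace(lead = 0, t_end = 1,
                      gaze_x = function(t) rep(0.3, length(t)))
  expect_equal(gaze_velocity(const)$vx[i], rep(0, length(i)),
               tolerance = 1e-12)

  quad <- make_trace(lead = 0, t_end = 1, gaze_x = function(t) t^2)
  vq <- gaze_velocity(quad)
  expect_equal(vq$vx[i], 2 * quad$t[i], tolerance = 1e-9)

  expect_error(gaze_velocity(make_trace(lead = 0, t_end = 0.004)),
               "5 samples")
})

test_that("velocity thresholds use the median estimator, with a floor", {
  set.seed(8)
  v <- rnorm(5000)
  eta <- velocity_threshold(v, v, cfg)
  sd_med <- sqrt(median(v^2) - median(v)^2)
  expect_equal(unname(eta[1]), 15 * sd_med, tolerance = 1e-12)

  eta2 <- velocity_threshold(2 * v, 2 * v, cfg)
  expect_equal(unname(eta2), unname(2 * eta), tolerance = 1e-12)

  flat <- rep(0.5, 200)
  eta3 <- velocity_threshold(flat, flat, cfg)
  expect_equal(unname(eta3[1]), 15 * cfg$ms_velocity_floor_deg_s)

  expect_error(velocity_threshold(rnorm(50), rnorm(50), cfg), "100")
})

# fixation trace with raised-cosine saccades injected at known onsets
inject_saccades <- function(onsets, amp = 0.5, dur = 0.012, noise = 0.005,
                            t_end = 3, fs = 500, seed = 1) {
  set.seed(seed)
  t <- (0:round(t_end * fs)) / fs
  gx <- rnorm(length(t), 0, noise)
  gy <- rnorm(length(t), 0, noise)
  for (on in onsets) {
    u <- pmin(pmax((t - on) / dur, 0), 1)
    gx <- gx + amp * (u - sin(2 * pi * u) / (2 * pi))
  }
  sample_trace(t, rep(10, length(t)), gx, gy, sampling_rate = fs)
}

test_that("injected saccades are recovered; sub-6 ms events are rejected", {
  tr <- inject_saccades(1.5)
  ev <- detect_microsaccades(tr, cfg)
  expect_identical(nrow(ev), 1L)
  expect_lt(abs(ev$onset_s - 1.5), 2 / 500 + 1e-9)
  expect_gte(ev$duration_s, cfg$ms_min_duration_s)
  expect_equal(ev$amplitude_deg, 0.5, tolerance = 0.1)

  # a 4 ms (2-sample) tracker glitch: its suprathreshold velocity samples
  # do not form a run persisting 6 ms, so the duration rule rejects it
  short <- inject_saccades(numeric(0), t_end = 3, seed = 2)
  i0 <- 750
  short$gaze_x[i0 + 0:1] <- short$gaze_x[i0 + 0:1] + 0.08
  expect_identical(nrow(detect_microsaccades(short, cfg)), 0L)
})

test_that("fixation noise alone yields no detections at k = 15", {
  n_events <- vapply(1:40, function(s) {
    tr <- inject_saccades(numeric(0), t_end = 2, seed = s)
    nrow(detect_microsaccades(tr, cfg))
  }, numeric(1))
  expect_identical(sum(n_events), 0)
})

test_that("detection is invariant to affine changes of gaze units", {
  tr <- inject_saccades(c(0.8, 2.1))
  ev1 <- detect_microsaccades(tr, cfg)
  tr2 <- tr
  tr2$gaze_x <- 3 * tr$gaze_x + 5
  tr2$gaze_y <- 3 * tr$gaze_y - 2
  ev2 <- detect_microsaccades(tr2, cfg)
  expect_equal(ev1$onset_s, ev2$onset_s)
  expect_equal(ev2$amplitude_deg, 3 * ev1$amplitude_deg, tolerance = 1e-9)
})

test_that("events overlapping expanded blink windows are discarded", {
  tr <- inject_saccades(c(0.8, 2.1))
  tr$blink_intervals <- rbind(c(2.0, 2.2))
  ev <- detect_microsaccades(tr, cfg)
  expect_identical(nrow(ev), 1L)
  expect_lt(abs(ev$onset_s - 0.8), 0.01)
})

test_that("rate curves are unit-area Gaussians at event onsets", {
  fs <- 500
  t <- (0:(6 * fs)) / fs
  one <- data.frame(onset_s = 3)
  rc <- rate_curve(one, t, cfg)
  expect_lt(abs(sum(rc$rate) / fs - 1), 1e-6)
  expect_equal(max(rc$rate), 1 / (0.02 * sqrt(2 * pi)), tolerance = 1e-3)
  expect_equal(rc$t[which.max(rc$rate)], 3, tolerance = 1e-9)

  none <- rate_curve(data.frame(onset_s = numeric(0)), t, cfg)
  expect_identical(none$rate, numeric(length(t)))

  two <- rate_curve(data.frame(onset_s = c(2, 3)), t, cfg)
  expect_equal(two$rate,
               dnorm(t, 2, 0.02) + dnorm(t, 3, 0.02), tolerance = 1e-12)
})

test_that("mean rate recovers the generating Poisson intensity", {
  expect_equal(mean_rate(rate_curve(data.frame(onset_s = numeric(0)),
                                    (0:2000) / 500, cfg), 1.5, cfg), 0)
  # single event centred in a long window contributes ~ 1/L
  fs <- 500
  t <- (-3 * fs):(12 * fs) / fs
  rc <- rate_curve(data.frame(onset_s = 5), t, cfg)
  w <- metric_window(9.5, pipeline_config(metric_pre_s = 0.0,
                                          metric_post_s = 0.5))
  L <- diff(w)
  m <- mean(rc$rate[t >= w[1] & t <= w[2]])
  expect_equal(m, 1 / L, tolerance = 0.01)

  set.seed(10)
  rates <- replicate(60, {
    onsets <- sort(runif(rpois(1, 2 * 4), 0, 4))
    t4 <- (0:(4 * 500)) / 500
    rc <- rate_curve(data.frame(onset_s = onsets), t4, cfg)
    mean(rc$rate[t4 >= 0.5 & t4 <= 3.5])
  })
  expect_lt(abs(mean(rates) - 2), 3 * sd(rates) / sqrt(60) + 0.1)
})

test_that("group rate curves show post-onset inhibition then recovery", {
  sc <- sim_config(n_participants = 2, seed = 21, duration_range = c(2, 2),
                   ms_base_rate_hz = 2, ms_inhibition_depth = 0.8,
                   ms_inhibition_t_s = 0.5)
  sim <- simulate_experiment(sc)
  t <- sim$traces[[1]]$t
  acc <- numeric(length(t))
  for (i in seq_along(sim$traces)) {
    ev <- sim$truth[[i]]$microsaccades
    acc <- acc + rate_curve(ev, t, cfg)$rate
  }
  acc <- acc / length(sim$traces)
  pre <- mean(acc[t > -2 & t < -0.1])
  dip <- mean(acc[t > 0.1 & t < 0.4])
  post <- mean(acc[t > 1 & t < 2])
  expect_lt(dip, 0.6 * pre)
  expect_gt(post, dip)
})
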