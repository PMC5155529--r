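test_that("integrate_flow computes the cumulative trapezoidal integral", {
  fs <- 1000
  # all-zero flow stays zero
  z <- pressure_trace(numeric(2000), fs)
  expect_equal(integrate_flow(z, "none")$samples, numeric(2000))

  # 1 mV rectangular pulse lasting 1 s: terminal volume exactly 1 mV s
  x <- c(numeric(500), rep(1, 1000), numeric(500))
  tr <- pressure_trace(x, fs)
  v <- integrate_flow(tr, "none")$samples
  expect_equal(v[length(v)], 1.0, tolerance = 1e-6)

  # sine flow: volume peaks at 1/pi at t = 0.5 s (closed form)
  t <- seq(0, 1, by = 1 / fs)
  s <- pressure_trace(sin(2 * pi * t), fs)
  vs <- integrate_flow(s, "none")$samples
  expect_equal(max(vs), 1 / pi, tolerance = 1e-4)
  expect_equal((which.max(vs) - 1) / fs, 0.5, tolerance = 1e-3)

  expect_error(integrate_flow(pressure_trace(0.5, fs), "none"), "short")
})

test_that("integration is linear when drift correction is off", {
  fs <- 200
  set.seed(11)
  x <- rnorm(1000); y <- rnorm(1000)
  vx <- integrate_flow(pressure_trace(x, fs), "none")$samples
  vy <- integrate_flow(pressure_trace(y, fs), "none")$samples
  vxy <- integrate_flow(pressure_trace(2 * x - 3 * y, fs), "none")$samples
  expect_equal(vxy, 2 * vx - 3 * vy, tolerance = 1e-10)
})

test_that("calibration recovers the true factor and errors on few pulses", {
  s <- sim_breath_trace(breath_sim_params(duration_s = 10, seed = 21,
                                          cal_factor_ul_per_mv = 8))
  cal <- calibrate(s$cal_trace, 20)
  expect_s3_class(cal, "calibration_factor")
  expect_equal(cal$ul_per_mv, 8, tolerance = 0.02)

  # mean-of-peaks definition: pulse heights {1.9, 2.0, 2.1} with 20 ul
  # injections give 10 ul/mV; build the trace from raised-sine derivatives
  fs <- 1000
  mk_flow <- function(amps, onsets, T) {
    dur <- max(onsets) + T + 0.5
    tt <- (seq_len(dur * fs) - 1) / fs
    f <- numeric(length(tt))
    for (i in seq_along(amps)) {
      inside <- tt >= onsets[i] & tt < onsets[i] + T
      f[inside] <- f[inside] +
        amps[i] * (pi / T) * sin(2 * pi * (tt[inside] - onsets[i]) / T)
    }
    f
  }
  tr <- pressure_trace(mk_flow(c(1.9, 2, 2.1), c(0.5, 1.5, 2.5), 0.2), fs)
  expect_equal(calibrate(tr, 20)$ul_per_mv, 10, tolerance = 1e-3)

  tr2 <- pressure_trace(mk_flow(c(2, 2), c(0.5, 1.5), 0.2), fs)
  expect_error(calibrate(tr2, 20), "calibration error")
})

test_that("segmentation recovers the noiseless breath schedule exactly", {
  s <- noiseless_sim()
  b <- segment_breaths(integrate_flow(s$trace))
  expect_equal(nrow(b$breaths), 30)
  expect_true(all(abs(b$ibis_s - 1 / 3) <= 1 / s$trace$sampling_rate_hz))
  expect_equal(b$breaths$amplitude_mv, rep(1, 30), tolerance = 0.01)
})

test_that("flatline yields no breaths and short waveforms error", {
  fs <- 100
  v <- integrate_flow(pressure_trace(numeric(3000), fs), "none")
  expect_equal(nrow(segment_breaths(v)$breaths), 0)
  vshort <- structure(list(samples = numeric(5), sampling_rate_hz = fs,
                           drift_corrected = "none"),
                      class = "volume_waveform")
  expect_error(segment_breaths(vshort, refractory_s = 1), "refractory")
})

test_that("segmentation is invariant under uniform gain", {
  s <- sim_breath_trace(breath_sim_params(duration_s = 30, seed = 13))
  v <- integrate_flow(s$trace)
  v2 <- v
  v2$samples <- v$samples * 7.3
  b1 <- segment_breaths(v); b2 <- segment_breaths(v2)
  expect_equal(nrow(b1$breaths), nrow(b2$breaths))
  expect_equal(b1$ibis_s, b2$ibis_s)
  expect_equal(b2$breaths$amplitude_mv, 7.3 * b1$breaths$amplitude_mv)
})

test_that("onsets are recovered within 25 ms at nominal noise", {
  s <- sim_breath_trace(breath_sim_params(duration_s = 150, seed = 17))
  b <- segment_breaths(integrate_flow(s$trace))
  truth <- s$truth$breath_onsets_s
  d <- vapply(truth, function(o) min(abs(b$breaths$onset_s - o)),
              numeric(1))
  expect_gte(mean(d <= 0.025), 0.99)
  # spurious detections: breaths not matching any true onset
  d2 <- vapply(b$breaths$onset_s, function(o) min(abs(truth - o)),
               numeric(1))
  expect_lte(mean(d2 > 0.025), 0.01)
})

test_that("window selection applies the cumulative-data rules", {
  # artifact-free epoch: ventilation policy returns the last 300 s
  tr <- dummy_trace(400, room_air_epoch(400))
  w <- select_windows(tr, "room_air", "ventilation")
  expect_equal(nrow(w$segments), 1)
  expect_equal(w$segments$start_s, 100)
  expect_equal(w$cumulative_s, 300)
  expect_false(w$insufficient)

  # runs of 8 s and 9 s only: nothing qualifies under the 10 s rule
  mask <- data.frame(start_s = c(8, 17), end_s = c(9, 30))
  tr2 <- dummy_trace(30, room_air_epoch(30), mask)
  w2 <- select_windows(tr2, "room_air", "ventilation")
  expect_equal(nrow(w2$segments), 0)
  expect_true(w2$insufficient)

  # runs 30 + 20 + 15 = 65 s >= 60 s: accepted
  mask3 <- data.frame(start_s = c(30, 55, 80), end_s = c(35, 65, 300))
  tr3 <- dummy_trace(300, room_air_epoch(300), mask3)
  w3 <- select_windows(tr3, "room_air", "ventilation")
  expect_equal(w3$cumulative_s, 65)
  expect_false(w3$insufficient)

  # pattern policy caps cumulative coverage at 600 s
  tr4 <- dummy_trace(700, room_air_epoch(700))
  w4 <- select_windows(tr4, "room_air", "pattern")
  expect_equal(w4$cumulative_s, 600)

  expect_error(select_windows(tr, "nonsense", "ventilation"), "epoch")
  expect_error(select_windows(tr, "hypoxia", "ventilation"), "not present")
})

test_that("ventilation summary implements the rate/volume/product identities", {
  s <- noiseless_sim()
  cal <- calibrate(s$cal_trace)
  b <- segment_breaths(integrate_flow(s$trace))
  w <- select_windows(s$trace, "room_air", "ventilation", min_total_s = 5)
  vs <- ventilation_summary(b, cal, w, condition = "room_air")
  expect_equal(vs$vf, 60 * vs$n_breaths / w$cumulative_s)
  expect_equal(vs$ve, vs$vf * vs$vt)
  # noiseless recovery of planted values
  expect_equal(vs$vf, 180, tolerance = 0.01)
  expect_equal(vs$vt, 10, tolerance = 0.02)

  ins <- w; ins$insufficient <- TRUE
  expect_error(ventilation_summary(b, cal, ins), "insufficient")
})
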