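test_that("rms and differentiate follow closed-form values", {
  expect_equal(rms(time_series(c(3, 4), 10)), sqrt(12.5))
  expect_equal(rms(time_series(rep(-2, 50), 10)), 2)
  # sinusoid over integer periods: RMS = A/sqrt(2)
  t <- seq(0, 10 - 1 / 100, by = 1 / 100)
  expect_equal(rms(time_series(3 * sin(2 * pi * t), 100)), 3 / sqrt(2),
               tolerance = 1e-6)

  # ramp derivative is the slope, constants differentiate to zero
  r <- differentiate(time_series(2.5 * t, 100, units = "deg"))
  expect_equal(unique(round(r$values, 9)), 2.5)
  expect_equal(r$units, "deg/s")
  expect_true(all(differentiate(time_series(rep(1, 10), 100))$values == 0))
  # sinusoid derivative: relative error bounded by (2 pi f / rate)^2 / 6
  f <- 3; rate <- 100
  d <- differentiate(time_series(sin(2 * pi * f * t), rate))
  interior <- 3:(length(t) - 2)
  relerr <- max(abs(d$values[interior] - 2 * pi * f * cos(2 * pi * f * t[interior]))) /
    (2 * pi * f)
  expect_lt(relerr, (2 * pi * f / rate)^2 / 6)
  expect_error(rms(time_series(c(1, 2), 10, valid = c(FALSE, FALSE))), "valid")
})

test_that("differentiate then cumulative integration recovers smooth signals", {
  t <- seq(0, 10, by = 1 / 2000)
  x <- time_series(sin(2 * pi * 0.7 * t) + 0.3 * cos(2 * pi * 1 * t), 2000)
  xi <- integrate_ts(differentiate(x))
  dev <- x$values - xi$values - (x$values[1] - xi$values[1])
  expect_lt(max(abs(dev)), 1e-6 * diff(range(x$values)))
})

test_that("group-delay correction shifts by the nearest sample and logs the residual", {
  x <- time_series(c(rep(0, 50), 1, rep(0, 49)), 100)
  y <- correct_group_delay(x, 0.1)     # 10 samples
  expect_equal(which.max(y$values), 41)
  expect_identical(correct_group_delay(x, 0)$values, x$values)
  # 48 ms at 2160 samples/s: 103.68 samples -> 104 with residual -0.32
  z <- time_series(rnorm(5000), 2160)
  zc <- correct_group_delay(z, 0.048)
  expect_equal(attr(zc, "subsample_residual"), 103.68 - 104, tolerance = 1e-9)
  expect_identical(zc$values[1], z$values[105])
  expect_false(any(zc$valid[(5000 - 103):5000]))
  expect_error(correct_group_delay(x, 10), "duration")
  expect_error(correct_group_delay(x, -1), "non-negative")
})

test_that("trunk orientation and A-P displacement follow the marker geometry", {
  l1 <- marker_track(c(0, 0, 0, 1), c(0, 0, 0, 0), 100)
  t1 <- marker_track(c(0, 10, -5, 1), c(10, 10, 5 * sqrt(3), 0), 100)
  ang <- trunk_orientation(l1, t1)
  expect_equal(ang$values[1], 0)
  expect_equal(ang$values[2], 45)
  expect_equal(ang$values[3], -30, tolerance = 1e-9)
  expect_false(ang$valid[4])         # coincident markers
  expect_true(all(ang$valid[1:3]))

  ap <- ap_displacement(marker_track(c(1, 2, 3), c(0, 0, 0), 100))
  expect_equal(ap$values, c(1, 2, 3))
  expect_equal(ap$units, "cm")
  expect_error(trunk_orientation(l1, marker_track(1, 1, 50)), "share")
})

test_that("EMG envelope is zero-lag, removes DC, and tracks rectified amplitude", {
  rate <- 2160
  t <- seq(0, 4 - 1 / rate, by = 1 / rate)
  # constant input: high-pass removes DC (away from filter edge transients)
  env_dc <- emg_envelope(time_series(rep(2, length(t)), rate))$values
  expect_lt(max(abs(env_dc[t > 0.5 & t < 3.5])), 1e-6)
  # 100-Hz sinusoid of amplitude A: envelope ~ mean |A sin| = 2A/pi
  A <- 1.7
  env <- emg_envelope(time_series(A * sin(2 * pi * 100 * t), rate))
  interior <- t > 0.5 & t < 3.5
  expect_equal(mean(env$values[interior]), 2 * A / pi, tolerance = 0.02)
  # time-reversal symmetry of the zero-lag cascade (away from the edges,
  # where the finite forward-backward passes have transients)
  set.seed(1)
  x <- rnorm(20 * rate)
  fwd <- emg_envelope(time_series(x, rate))$values
  rev_ <- emg_envelope(time_series(rev(x), rate))$values
  interior <- seq(5 * rate, 15 * rate)
  expect_equal(fwd[interior], rev_[length(x) + 1 - interior],
               tolerance = 1e-6)
  # symmetric burst: envelope peak at the burst center
  burst <- exp(-((t - 2) / 0.05)^2) * sin(2 * pi * 150 * t)
  env2 <- emg_envelope(time_series(burst, rate))
  expect_lt(abs(t[which.max(env2$values)] - 2), 0.01)
  expect_error(emg_envelope(time_series(x, 100)), "200")
})

test_that("perturbation generator matches its spectral design", {
  # zero spectral density -> all-zero signal
  z <- generate_perturbation(visual_spec_scaled(0, duration = 30), seed = 1)
  expect_true(all(z$values == 0))
  # cutoff above Nyquist rejected with the offending stage named
  bad <- perturbation_spec("visual", 1, list(list(family = "butter", order = 2L, cutoff = 40)),
                           duration = 30, ramp = 2, rate = 100)
  expect_error(generate_perturbation(bad, 1), "Nyquist|rate/4")
  # deterministic given seed
  a <- generate_perturbation(visual_spec_scaled(1, duration = 30), seed = 7)
  b <- generate_perturbation(visual_spec_scaled(1, duration = 30), seed = 7)
  expect_identical(a$values, b$values)
  # ramps reach zero at the endpoints
  expect_equal(a$values[1], 0)
  expect_equal(a$values[length(a$values)], 0)

  # PSD shape: ensemble Welch PSD of the motor chain matches
  # psd_level * |H(f)|^2 below the cutoff within 10%
  spec <- motor_perturbation_spec(rate = 120, duration = 250)
  nseg <- 0; acc <- NULL
  for (s in 1:12) {
    x <- generate_perturbation(spec, seed = s)
    v <- x$values[x$rate * 5 + seq_len(120 * 240)]     # interior segment
    sp <- spec.pgram(ts(v, frequency = 120), spans = c(51, 51), taper = 0.1,
                     plot = FALSE, detrend = TRUE)
    acc <- if (is.null(acc)) sp$spec else acc + sp$spec
    nseg <- nseg + 1
  }
  psd <- 2 * acc / nseg                                # one-sided
  f <- sp$freq
  sel <- f > 0.2 & f < 0.8 * 4
  bt <- signal::butter(8, 4 / 60, type = "low")
  Hmag2 <- Mod(signal::freqz(bt, f, Fs = 120)$h)^2
  expect_lt(max(abs(psd[sel] / (1.1 * Hmag2[sel]) - 1)), 0.10)
})

test_that("visual chain variance matches the first-order noise-bandwidth closed form", {
  # integral of S(f) df = 150 * 0.02 * pi/2 deg^2 (5-Hz stage negligible):
  # interior-segment pooled RMS within 3% of sqrt(4.712) = 2.171 deg
  spec <- visual_spec_scaled(1)
  msq <- 0; n <- 40
  for (s in 1:n) {
    x <- generate_perturbation(spec, seed = 100 + s)
    v <- x$values[x$rate * 20 + seq_len(120 * 220)]    # skip ramps and filter startup
    msq <- msq + mean(v^2)
  }
  expect_equal(sqrt(msq / n), sqrt(150 * 0.02 * pi / 2), tolerance = 0.03)
})
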