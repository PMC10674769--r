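test_that("OFS two-point calibration maps anchor voltages to anchor angles", {
  cal <- list(ofs_v_flex0 = 2.0, ofs_v_ext140 = 1.0)
  a <- calibrate_ofs(c(2.0, 1.5, 1.0), cal, rate = 100)
  expect_equal(a$angle, c(0, 70, 140))
  # affine and strictly monotone between the anchors
  v <- seq(2.0, 1.0, by = -0.1)
  ang <- calibrate_ofs(v, cal, rate = 100)$angle
  expect_true(all(diff(ang) > 0))
  expect_equal(diff(ang), rep(diff(ang)[1], length(ang) - 1))
  expect_error(calibrate_ofs(1.5, list(ofs_v_flex0 = 1, ofs_v_ext140 = 1), 100),
               "distinct")
})

test_that("angle low-pass has unit DC gain, passes the cycle band, kills noise band", {
  rate <- 100
  t <- seq(0, 60, by = 1 / rate)
  const <- make_angle_series(rep(70, 1000), rate)
  expect_equal(lowpass_angle(const)$angle, rep(70, 1000), tolerance = 1e-9)
  slow <- lowpass_angle(make_angle_series(sin(2 * pi * 0.1 * t), rate))
  expect_equal(diff(range(slow$angle)) / 2, 1, tolerance = 0.05)
  fast <- lowpass_angle(make_angle_series(sin(2 * pi * 5 * t), rate))
  expect_lt(max(abs(fast$angle)), 0.1)
  # DC-shift commutation: filtering x + c equals filtering x, plus c
  x <- sin(2 * pi * 0.2 * t) + rnorm(length(t), 0, 0.1)
  y0 <- lowpass_angle(make_angle_series(x, rate))$angle
  y1 <- lowpass_angle(make_angle_series(x + 17, rate))$angle
  expect_equal(y1, y0 + 17, tolerance = 1e-8)
  expect_error(lowpass_angle(const, fc = 60), "Nyquist")
})

test_that("MVC is the mean of three per-recording plateau summaries", {
  expect_equal(compute_mvc(list(rep(1, 100), rep(2, 100), rep(3, 100))), 2)
  expect_equal(compute_mvc(list(rep(4, 50), rep(4, 50), rep(4, 50))), 4)
  expect_equal(compute_mvc(list(rep(0.5, 10), rep(0.5, 10), rep(2, 10))), 1)
  expect_error(compute_mvc(list(rep(1, 10), rep(2, 10))), "exactly 3")
})

test_that("EMG conditioning rejects DC, tracks a rectified sine, self-normalizes", {
  rate <- 1024
  dc <- condition_emg(rep(0.8, 6000), mvc = 1, rate = rate)
  expect_lt(max(abs(dc$bandpassed)), 1e-6)
  expect_lt(max(dc$envelope_pct_mvc), 1e-4)
  t <- seq(0, 6, by = 1 / rate)
  s <- condition_emg(sin(2 * pi * 100 * t), mvc = 2, rate = rate)
  interior <- seq(2 * rate, 4 * rate)
  # rectified unit sine averages 2/pi; divided by MVC=2, in percent
  expect_equal(mean(s$envelope_pct_mvc[interior]), (2 / pi) / 2 * 100,
               tolerance = 0.02)
  expect_lt(sd(s$envelope_pct_mvc[interior]), 0.5)
  # conditioning a signal against its own envelope level gives ~100 %MVC
  own <- condition_emg(sin(2 * pi * 100 * t), mvc = 2 / pi, rate = rate)
  expect_equal(mean(own$envelope_pct_mvc[interior]), 100, tolerance = 2)
  expect_error(condition_emg(t, mvc = 0), "positive")
  expect_error(condition_emg(t, mvc = 1, rate = 512), "900")
})

test_that("EMG envelope is invariant to sign flip of the raw signal", {
  set.seed(2)
  x <- rnorm(8000)
  a <- condition_emg(x, mvc = 1)
  b <- condition_emg(-x, mvc = 1)
  expect_equal(a$envelope_pct_mvc, b$envelope_pct_mvc, tolerance = 1e-10)
})

test_that("IMU smoothing preserves constants, spreads impulses, shrinks noise", {
  rate <- 128
  m <- matrix(5, 200, 6, dimnames = list(NULL, colnames <- c(
    "GyroX", "GyroY", "GyroZ", "AccX", "AccY", "AccZ"
  )))
  expect_equal(smooth_imu(m, 30, rate), m, ignore_attr = TRUE)
  # 30 ms at 128 Hz rounds to a 5-sample window: impulse -> 1/5 rectangle
  imp <- matrix(0, 101, 6, dimnames = list(NULL, colnames))
  imp[51, ] <- 1
  sm <- smooth_imu(imp, 30, rate)
  expect_equal(sm[49:53, 1], rep(1 / 5, 5))
  expect_equal(sum(sm[, 1]), 1)
  set.seed(4)
  noise <- matrix(rnorm(6 * 20000, 0, 2), ncol = 6,
                  dimnames = list(NULL, colnames))
  smn <- smooth_imu(noise, 30, rate)
  expect_equal(sd(smn[100:19900, 3]), 2 / sqrt(5), tolerance = 0.05)
  expect_error(smooth_imu(m, window_ms = 1, rate = 128), "one sample")
})

test_that("baseline subtraction removes the anatomical offset channel-wise", {
  ch <- c("GyroX", "GyroY", "GyroZ", "AccX", "AccY", "AccZ")
  base <- setNames(1:6, ch)
  m <- matrix(rep(1:6, each = 50), 50, 6, dimnames = list(NULL, ch))
  expect_true(all(subtract_baseline(m, base) == 0))
  expect_equal(subtract_baseline(m, setNames(rep(0, 6), ch)), m)
  ramp <- m + matrix(seq_len(50), 50, 6)
  expect_equal(subtract_baseline(ramp, base),
               matrix(seq_len(50), 50, 6, dimnames = list(NULL, ch)))
  expect_error(subtract_baseline(m, base[1:4]), "missing baseline")
})
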