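test_that("window statistics match hand computations", {
  expect_equal(window_stats(c(1, 1, 1, 1)),
               c(mean = 1, std = 0, rms = 1, amplitude = 0))
  # two-point case: sample (n-1) standard deviation
  expect_equal(window_stats(c(0, 2)),
               c(mean = 1, std = sqrt(2), rms = sqrt(2), amplitude = 2))
  t <- seq(0, 10 - 1e-3, by = 1e-3)
  s <- sin(2 * pi * t) # whole periods
  expect_equal(window_stats(s)[["rms"]], 1 / sqrt(2), tolerance = 1e-3)
  expect_error(window_stats(3), "at least 2")
})

test_that("rms^2 >= mean^2 with equality iff the segment is constant", {
  set.seed(10)
  for (i in 1:20) {
    x <- rnorm(50, mean = runif(1, -5, 5), sd = runif(1, 0, 2))
    ws <- window_stats(x)
    expect_gte(ws[["rms"]]^2 + 1e-12, ws[["mean"]]^2)
  }
  ws <- window_stats(rep(2.5, 10))
  expect_equal(ws[["rms"]]^2, ws[["mean"]]^2)
})

test_that("spectral indices recover pure tones and mixtures", {
  fs <- 1024
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  sp <- spectral_stats(sin(2 * pi * 100 * t), fs)
  expect_equal(sp[["mnf"]], 100, tolerance = 0.01)
  expect_equal(sp[["mdf"]], 100, tolerance = 0.01)
  two <- sin(2 * pi * 10 * t) + sin(2 * pi * 30 * t)
  expect_equal(spectral_stats(two, fs)[["mnf"]], 20, tolerance = 0.02)
  expect_error(spectral_stats(rep(0, 64), fs), "all-zero")
  expect_error(spectral_stats(1:4, fs), "at least 8")
})

test_that("flat-band noise has centroid and median at the band midpoint", {
  # oracle: construct an exactly flat band in the Fourier domain
  fs <- 1024
  n <- 16384
  set.seed(6)
  spec <- rep(0 + 0i, n)
  f <- (0:(n - 1)) * fs / n
  band <- f >= 60 & f <= 180
  phase <- runif(sum(band), 0, 2 * pi)
  spec[band] <- exp(1i * phase)
  spec[n + 2 - which(band)] <- Conj(spec[band])
  x <- Re(fft(spec, inverse = TRUE)) / n
  sp <- spectral_stats(x, fs)
  expect_equal(sp[["mnf"]], 120, tolerance = 0.03)
  expect_equal(sp[["mdf"]], 120, tolerance = 0.03)
})

test_that("MDF splits cumulative power at one half, verified by brute force", {
  fs <- 512
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(1024) + sin(2 * pi * sample(20:200, 1) * seq_len(1024) / fs)
    mdf <- spectral_stats(x, fs)[["mdf"]]
    # independent brute-force cumulative sum over a Hann periodogram
    w <- 0.5 - 0.5 * cos(2 * pi * (0:1023) / 1023)
    p <- (Mod(fft(x * w))^2)[2:513]
    fr <- (1:512) * fs / 1024
    below <- sum(p[fr < mdf])
    at <- sum(p[fr <= mdf])
    expect_lt(below, sum(p) / 2)
    expect_gte(at, sum(p) / 2)
  }
})

test_that("IMNF agrees with known instantaneous-frequency structure", {
  fs <- 1024
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  expect_equal(imnf(sin(2 * pi * 100 * t), fs), 100, tolerance = 0.05)
  # linear chirp 50 -> 150 Hz: time-averaged instantaneous frequency 100 Hz
  ph <- 2 * pi * cumsum(seq(50, 150, length.out = length(t))) / fs
  expect_equal(imnf(sin(ph), fs), 100, tolerance = 0.10)
  expect_error(imnf(rep(0, 64), fs), "all-zero")
  expect_error(imnf(rnorm(16), fs), "at least 32")
})

test_that("IMNF of stationary band noise approximates the Fourier MNF", {
  fs <- 1024
  set.seed(8)
  bp <- signal::butter(4, c(60, 160) / (fs / 2), "pass")
  x <- signal::filtfilt(bp, rnorm(12288))[3000:11000]
  expect_equal(imnf(x, fs, fmin = 1), spectral_stats(x, fs)[["mnf"]],
               tolerance = 0.10)
})

test_that("frequency indices live in (0, Nyquist]", {
  fx <- tiny_conditioned()
  segs <- slice_streams(fx$cond, fx$windows)
  for (s in segs[c(1, length(segs))]) {
    sp <- spectral_stats(s$emg_bandpassed, fx$cond$fs$emg)
    im <- imnf(s$emg_bandpassed, fx$cond$fs$emg, fmin = 1)
    expect_true(all(sp > 0) && all(sp <= fx$cond$fs$emg / 2))
    expect_true(im > 0 && im <= fx$cond$fs$emg / 2)
    spa <- spectral_stats(s$angle - mean(s$angle), fx$cond$fs$ofs)
    expect_true(all(spa > 0) && all(spa <= fx$cond$fs$ofs / 2))
  }
})

test_that("feature catalog counts follow the sensor selection", {
  expect_length(feature_names(), 63)
  expect_length(feature_names("emg"), 7)
  expect_length(feature_names("ofs"), 8)
  expect_length(feature_names("imu1"), 24)
  expect_length(feature_names(c("imu1", "imu2")), 48)
  expect_length(feature_names(c("imu1", "imu2", "ofs")), 56)
  expect_false(any(duplicated(feature_names())))
  fx <- tiny_conditioned()
  seg <- slice_streams(fx$cond, fx$windows)[[1]]
  expect_length(assemble_features(seg, fx$cond$fs), 63)
  expect_length(assemble_features(seg, fx$cond$fs, "emg"), 7)
  expect_length(assemble_features(seg, fx$cond$fs, "ofs"), 8)
  expect_length(assemble_features(seg, fx$cond$fs, "imu2"), 24)
  broken <- seg
  broken$emg_envelope <- NULL
  expect_error(assemble_features(broken, fx$cond$fs, "emg"), "missing")
})

test_that("first-cycle normalization maps time-amplitude features to exactly 1", {
  fx <- tiny_conditioned()
  ft <- extract_trial_features(fx$cond, fx$windows)
  nf <- normalize_features(ft)
  freq_cols <- grep("_(MNF|MDF|IMNF)$", feature_names(), value = TRUE)
  amp_cols <- setdiff(feature_names(), freq_cols)
  expect_true(all(as.numeric(nf[1, amp_cols]) == 1))
  expect_equal(nf[freq_cols], ft[freq_cols])
  # plain ratio on later cycles
  expect_equal(nf$EMG_mean[5], ft$EMG_mean[5] / ft$EMG_mean[1])
})

test_that("normalization refuses a zero first-cycle value, naming the feature", {
  tab <- toy_features(2, 5)
  tab$FIB_ROM[tab$subject_id == "S01" & tab$cycle == 1] <- 0
  expect_error(normalize_features(tab), "FIB_ROM")
})

test_that("fatigue trends appear in the extracted per-cycle features", {
  fx <- tiny_conditioned()
  ft <- extract_trial_features(fx$cond, fx$windows)
  idx <- ft$cycle
  slope <- function(y) coef(lm(y ~ idx))[2]
  expect_gt(slope(ft$EMG_mean), 0)
  expect_lt(slope(ft$EMG_IMNF), 0)
  expect_gt(slope(ft$FIB_tnorm), 0)
  expect_lt(slope(ft$FIB_ROM), 0)
})
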