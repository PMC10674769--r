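#' Calibrate the optical-fiber voltage into an elbow-angle series
#'
#' Two-point linear characterization: each subject holds two known postures,
#' full flexion (0 deg) and extension (140 deg), and the recorded voltages
#' anchor an affine map from volts to degrees.
#'
#' @param voltage raw OFS voltage series (V).
#' @param cal calibration record with `ofs_v_flex0` and `ofs_v_ext140`.
#' @param rate sampling rate of the voltage series (Hz).
#' @return an `angle_series` list: `time` (s), `angle` (deg), `rate` (Hz).
#' @export
calibrate_ofs <- function(voltage, cal, rate) {
  v0 <- cal$ofs_v_flex0
  v140 <- cal$ofs_v_ext140
  if (!is.numeric(v0) || !is.numeric(v140) || v0 == v140) {
    stop("calibration voltages at 0 and 140 degrees must be distinct")
  }
  angle <- 140 * (voltage - v0) / (v140 - v0)
  structure(list(
    time = (seq_along(voltage) - 1L) / rate,
    angle = as.numeric(angle),
    rate = rate
  ), class = "angle_series")
}

#' Low-pass filter the elbow-angle series
#'
#' Zero-phase 4th-order Butterworth low-pass; the default 0.5 Hz cutoff keeps
#' the slow flexion-extension cycle (~0.2-0.25 Hz) and rejects measurement
#' noise without lagging the cycle boundaries used for segmentation.
#'
#' @param series an `angle_series` from [calibrate_ofs()].
#' @param fc cutoff frequency (Hz); must lie below the Nyquist frequency.
#' @return filtered `angle_series`, same length.
#' @export
lowpass_angle <- function(series, fc = 0.5) {
  stopifnot(inherits(series, "angle_series"))
  if (fc >= series$rate / 2) {
    stop("cutoff must lie below the Nyquist frequency (", series$rate / 2, " Hz)")
  }
  filt <- signal::butter(4, fc / (series$rate / 2), "low")
  series$angle <- zero_phase_filter(filt, series$angle,
                                    pad = round(10 * series$rate / fc))
  series
}

#' Maximum voluntary contraction from three repeated recordings
#'
#' The reference contraction level is measured three consecutive times (5 s
#' holds); each recording is summarized by the mean of its central 60% of
#' samples (discarding ramp-up and release), and the MVC is the mean of the
#' three summaries.
#'
#' @param recordings list of exactly three EMG envelope series (mV).
#' @return MVC level (mV).
#' @export
compute_mvc <- function(recordings) {
  if (!is.list(recordings) || length(recordings) != 3L) {
    stop("MVC requires exactly 3 recordings")
  }
  summaries <- vapply(recordings, function(x) {
    n <- length(x)
    lo <- max(1L, floor(0.2 * n) + 1L)
    hi <- min(n, ceiling(0.8 * n))
    mean(x[lo:hi])
  }, numeric(1))
  mean(summaries)
}

#' Condition the raw EMG: band-pass, MVC-normalize, rectify, envelope
#'
#' The raw biceps EMG is band-passed 15-450 Hz (4th-order Butterworth,
#' zero-phase, realized as cascaded high- and low-pass halves) to remove
#' motion drift and high-frequency noise. The amplitude path then divides by
#' the subject's MVC, rectifies, and applies a 200 ms moving-average window,
#' giving an envelope in %MVC. Spectral fatigue indices (MNF/MDF/IMNF) are
#' computed downstream on the band-passed signal, whose 15-450 Hz content the
#' envelope would destroy.
#'
#' @param raw raw EMG series (mV).
#' @param mvc MVC level (mV), positive.
#' @param rate EMG sampling rate (Hz); must exceed 900 Hz so the 450 Hz band
#'   edge is representable.
#' @param band band-pass corner frequencies (Hz).
#' @param envelope_ms moving-average window for the envelope (ms).
#' @return a `conditioned_emg` list: `bandpassed` (mV), `envelope_pct_mvc`
#'   (%MVC), `rate`.
#' @export
condition_emg <- function(raw, mvc, rate = 1024, band = c(15, 450),
                          envelope_ms = 200) {
  if (!is.numeric(mvc) || mvc <= 0) stop("MVC must be positive")
  if (rate <= 900) stop("EMG sampling rate must exceed 900 Hz")
  if (band[2] >= rate / 2) stop("upper band edge must lie below Nyquist")
  hp <- signal::butter(4, band[1] / (rate / 2), "high")
  lp <- signal::butter(4, band[2] / (rate / 2), "low")
  bandpassed <- zero_phase_filter(
    lp, zero_phase_filter(hp, raw, pad = round(10 * rate / band[1])),
    pad = 64
  )
  width <- round(envelope_ms / 1000 * rate)
  envelope <- moving_mean(abs(bandpassed) / mvc * 100, width)
  structure(list(
    bandpassed = bandpassed,
    envelope_pct_mvc = envelope,
    rate = rate
  ), class = "conditioned_emg")
}

#' Smooth IMU channels with a short moving average
#'
#' Centered moving average (default 30 ms, i.e. 5 samples at 128 Hz after
#' rounding to the nearest odd width) applied per channel; edges shrink the
#' window rather than pad.
#'
#' @param channels n x 6 matrix (GyroX..AccZ).
#' @param window_ms window length (ms).
#' @param rate IMU sampling rate (Hz).
#' @return smoothed matrix, same dimensions.
#' @export
smooth_imu <- function(channels, window_ms = 30, rate = 128) {
  width <- round(window_ms / 1000 * rate)
  if (width < 1L) {
    stop("smoothing window is shorter than one sample at ", rate, " Hz")
  }
  apply(channels, 2L, moving_mean, width = width)
}

#' Subtract each channel's anatomical baseline
#'
#' Removes the per-channel offset recorded during the 1-minute anatomical
#' hold (sensor bias plus gravity in the hold posture), so subsequent
#' measurements are expressed relative to the resting posture.
#'
#' @param channels n x 6 matrix with named columns.
#' @param baseline named numeric vector of per-channel baseline means.
#' @return matrix with baselines removed.
#' @export
subtract_baseline <- function(channels, baseline) {
  missing <- setdiff(colnames(channels), names(baseline))
  if (length(missing) > 0) {
    stop("missing baseline for channel(s): ", paste(missing, collapse = ", "))
  }
  sweep(channels, 2L, baseline[colnames(channels)], "-")
}

#' Run the full conditioning chain on one trial
#'
#' Calibrates and low-pass filters the elbow angle, conditions the EMG
#' against the trial's MVC, and baseline-subtracts and smooths both IMUs.
#'
#' @param trial a `sensor_trial`.
#' @param ofs_fc angle low-pass cutoff (Hz).
#' @param emg_band EMG band-pass corners (Hz).
#' @param imu_window_ms IMU smoothing window (ms).
#' @return a `conditioned_trial` list: `angle` (`angle_series`), `emg`
#'   (`conditioned_emg`), `imu_wrist`, `imu_neck`, `borg_events`, `fs`,
#'   `duration`, `subject_id`.
#' @export
condition_trial <- function(trial, ofs_fc = 0.5, emg_band = c(15, 450),
                            imu_window_ms = 30) {
  stopifnot(inherits(trial, "sensor_trial"))
  angle <- lowpass_angle(
    calibrate_ofs(trial$ofs_voltage, trial$calibration, trial$fs$ofs),
    fc = ofs_fc
  )
  emg <- condition_emg(trial$emg, trial$calibration$mvc_value,
                       rate = trial$fs$emg, band = emg_band)
  imu <- lapply(c(wrist = "wrist", neck = "neck"), function(site) {
    smooth_imu(
      subtract_baseline(trial[[paste0("imu_", site)]],
                        trial$calibration$imu_baseline[[site]]),
      window_ms = imu_window_ms, rate = trial$fs$imu
    )
  })
  structure(list(
    subject_id = trial$subject_id,
    angle = angle,
    emg = emg,
    imu_wrist = imu$wrist,
    imu_neck = imu$neck,
    borg_events = trial$borg_events,
    fs = trial$fs,
    duration = trial$duration
  ), class = "conditioned_trial")
}
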