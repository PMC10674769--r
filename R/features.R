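#' Time-domain window statistics
#'
#' The amplitude-family summary computed per repetition cycle on every
#' channel: arithmetic mean, sample (n-1) standard deviation, root mean
#' square, and amplitude (max minus min).
#'
#' @param segment numeric series of length >= 2.
#' @return named numeric vector `mean`, `std`, `rms`, `amplitude`.
#' @export
window_stats <- function(segment) {
  if (length(segment) < 2L) stop("segment must contain at least 2 samples")
  c(
    mean = mean(segment),
    std = stats::sd(segment),
    rms = sqrt(mean(segment^2)),
    amplitude = max(segment) - min(segment)
  )
}

# Hann-tapered one-sided periodogram; the zero-frequency bin (series mean)
# is excluded so MNF/MDF describe the oscillatory content.
periodogram_hann <- function(segment, rate) {
  n <- length(segment)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
  spec <- Mod(stats::fft(segment * w))^2
  k <- 2:(floor(n / 2) + 1L)
  list(freq = (k - 1L) * rate / n, power = spec[k])
}

#' Mean and median frequency of a segment's power spectrum
#'
#' MNF is the power-weighted mean frequency `sum(f * P) / sum(P)` and MDF the
#' smallest frequency at which cumulative power reaches half the total; both
#' are the canonical EMG spectral fatigue indices (they shift down as muscle
#' fiber conduction velocity drops). The spectrum is a Hann-tapered
#' periodogram.
#'
#' @param segment numeric series of length >= 8.
#' @param rate sampling rate (Hz).
#' @return named numeric vector `mnf`, `mdf` (Hz).
#' @export
spectral_stats <- function(segment, rate) {
  if (length(segment) < 8L) stop("segment must contain at least 8 samples")
  if (all(segment == 0)) stop("spectrum of an all-zero segment is undefined")
  pg <- periodogram_hann(segment, rate)
  total <- sum(pg$power)
  if (total <= 0) stop("spectrum of an all-zero segment is undefined")
  mnf <- sum(pg$freq * pg$power) / total
  mdf <- pg$freq[which(cumsum(pg$power) >= total / 2)[1L]]
  c(mnf = mnf, mdf = mdf)
}

#' Instantaneous mean frequency from the continuous wavelet transform
#'
#' Computes a complex-Morlet CWT (center frequency 1, bandwidth 1.5) on a
#' log-spaced frequency grid, forms the power-weighted instantaneous mean
#' frequency `sum(f |W(f,t)|^2) / sum(|W(f,t)|^2)` at every sample, and
#' returns its time average over the segment. Unlike MNF, the IMNF tracks
#' nonstationary spectral compression within a window, which is why it is a
#' preferred fatigue index for dynamic contractions.
#'
#' The frequency grid spans `[fmin, rate/2]`; `fmin` defaults to half a
#' cycle per segment length so the sub-hertz fundamental of a single
#' repetition's joint-angle window is covered; for EMG windows `fmin = 1` Hz
#' is used upstream.
#'
#' @param segment numeric series of length >= 32; demeaned internally.
#' @param rate sampling rate (Hz).
#' @param fmin lowest analysis frequency (Hz); default `rate / (2 * n)`.
#' @param voices frequency-grid resolution (voices per octave).
#' @param wavelet_fb Morlet bandwidth parameter.
#' @return IMNF (Hz).
#' @export
imnf <- function(segment, rate, fmin = NULL, voices = 8, wavelet_fb = 1.5) {
  n <- length(segment)
  if (n < 32L) stop("segment must contain at least 32 samples")
  if (all(segment == 0)) stop("IMNF of an all-zero segment is undefined")
  x <- segment - mean(segment)
  if (is.null(fmin)) fmin <- rate / (2 * n)
  fmax <- rate / 2
  if (fmin >= fmax) fmin <- fmax / 4
  n_oct <- log2(fmax / fmin)
  freqs <- sort(fmax / 2^(seq(0, n_oct,
                              length.out = max(2L, ceiling(n_oct * voices)))))
  npad <- 2^ceiling(log2(2L * n))
  xf <- stats::fft(c(x, rep(0, npad - n)))
  fgrid <- (0:(npad - 1L)) * rate / npad
  pos <- fgrid <= rate / 2 # analytic wavelet: positive frequencies only
  # Trapezoid quadrature over the log-spaced grid; the scalogram |W(f,t)|^2
  # is divided by f (constant-Q bandwidth correction) so it estimates the
  # local power spectral density rather than power-per-octave, and the
  # instantaneous centroid is comparable with the Fourier MNF.
  df <- diff(freqs)
  wq <- c(df[1] / 2, (df[-1] + df[-length(df)]) / 2, df[length(df)] / 2)
  num <- numeric(n)
  den <- numeric(n)
  fc_w <- 1
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    s <- fc_w / f # scale in seconds
    psi <- numeric(npad)
    psi[pos] <- exp(-pi^2 * wavelet_fb * (s * fgrid[pos] - fc_w)^2)
    w_row <- stats::fft(xf * psi, inverse = TRUE)[1:n] / npad
    psd <- Mod(w_row)^2 / f
    num <- num + wq[i] * f * psd
    den <- den + wq[i] * psd
  }
  ok <- den > 0
  if (!any(ok)) stop("IMNF of an all-zero segment is undefined")
  mean(num[ok] / den[ok])
}

#' Canonical feature names
#'
#' The 63-feature catalog, in canonical order: 24 per IMU (mean, std, RMS,
#' amplitude for each of GyroX, GyroY, GyroZ, AccX, AccY, AccZ; IMU1 = wrist
#' first, then IMU2 = neck), 8 from the OFS elbow angle (FIB_mean, FIB_std,
#' FIB_RMS, FIB_ROM, FIB_tnorm, FIB_MNF, FIB_MDF, FIB_IMNF) and 7 from the
#' EMG (EMG_mean, EMG_std, EMG_RMS, EMG_Amp, EMG_MNF, EMG_MDF, EMG_IMNF).
#'
#' @param sensors subset of `c("imu1", "imu2", "ofs", "emg")`.
#' @return character vector of feature names in canonical order.
#' @export
feature_names <- function(sensors = c("imu1", "imu2", "ofs", "emg")) {
  sensors <- match.arg(sensors, c("imu1", "imu2", "ofs", "emg"),
                       several.ok = TRUE)
  ch <- c("GyroX", "GyroY", "GyroZ", "AccX", "AccY", "AccZ")
  stats_nm <- c("mean", "std", "RMS", "Amp")
  imu_nm <- function(tag) {
    as.vector(t(outer(ch, stats_nm, function(c_, s_) paste(tag, c_, s_, sep = "_"))))
  }
  out <- character(0)
  if ("imu1" %in% sensors) out <- c(out, imu_nm("IMU1"))
  if ("imu2" %in% sensors) out <- c(out, imu_nm("IMU2"))
  if ("ofs" %in% sensors) {
    out <- c(out, paste0("FIB_", c("mean", "std", "RMS", "ROM", "tnorm",
                                   "MNF", "MDF", "IMNF")))
  }
  if ("emg" %in% sensors) {
    out <- c(out, paste0("EMG_", c("mean", "std", "RMS", "Amp",
                                   "MNF", "MDF", "IMNF")))
  }
  out
}

#' Assemble the per-cycle feature vector
#'
#' Computes the feature families for one repetition window: four time-domain
#' statistics per IMU channel (on the smoothed, baseline-subtracted
#' channels), eight angle features (time-domain statistics, ROM, the raw
#' cycle duration `FIB_tnorm`, and MNF/MDF/IMNF of the demeaned filtered
#' angle) and seven EMG features (time-domain statistics of the %MVC
#' envelope; MNF/MDF/IMNF of the band-passed signal).
#'
#' @param segment one element of [slice_streams()] output.
#' @param fs list of sampling rates (`ofs`, `emg`, `imu`).
#' @param sensors which sensors to include.
#' @return named numeric vector (`24 * #IMUs + 8 * OFS + 7 * EMG` values).
#' @export
assemble_features <- function(segment, fs,
                              sensors = c("imu1", "imu2", "ofs", "emg")) {
  sensors <- match.arg(sensors, c("imu1", "imu2", "ofs", "emg"),
                       several.ok = TRUE)
  out <- numeric(0)
  imu_feats <- function(m, tag) {
    if (is.null(m) || nrow(m) < 2L) stop(tag, " segment missing or too short")
    vals <- as.vector(apply(m, 2L, window_stats))
    stats::setNames(vals, feature_names(tolower(tag)))
  }
  if ("imu1" %in% sensors) out <- c(out, imu_feats(segment$imu_wrist, "IMU1"))
  if ("imu2" %in% sensors) out <- c(out, imu_feats(segment$imu_neck, "IMU2"))
  if ("ofs" %in% sensors) {
    a <- segment$angle
    if (is.null(a) || length(a) < 32L) stop("OFS segment missing or too short")
    ws <- window_stats(a)
    sp <- spectral_stats(a - mean(a), fs$ofs)
    out <- c(out, stats::setNames(
      c(ws[c("mean", "std", "rms", "amplitude")], segment$duration,
        sp["mnf"], sp["mdf"], imnf(a, fs$ofs)),
      feature_names("ofs")
    ))
  }
  if ("emg" %in% sensors) {
    env <- segment$emg_envelope
    bp <- segment$emg_bandpassed
    if (is.null(env) || length(env) < 32L) stop("EMG segment missing or too short")
    ws <- window_stats(env)
    sp <- spectral_stats(bp, fs$emg)
    out <- c(out, stats::setNames(
      c(ws[c("mean", "std", "rms", "amplitude")],
        sp["mnf"], sp["mdf"], imnf(bp, fs$emg, fmin = 1)),
      feature_names("emg")
    ))
  }
  out
}

#' Extract the per-cycle feature table of one trial
#'
#' Runs [assemble_features()] on every repetition window and binds the
#' results with the cycle metadata (subject, cycle index, Borg value, state).
#'
#' @param cond a `conditioned_trial`.
#' @param windows labeled window tibble from [label_cycles()].
#' @param sensors which sensors to include.
#' @return tibble: `subject_id`, `cycle`, `borg`, `state`, then one column
#'   per feature in canonical order.
#' @export
extract_trial_features <- function(cond, windows,
                                   sensors = c("imu1", "imu2", "ofs", "emg")) {
  segs <- slice_streams(cond, windows)
  meta_state <- if (nrow(windows) > 0 && "state" %in% names(windows)) {
    windows$state
  } else {
    factor(rep(NA_character_, length(segs)), levels = fatigue_states())
  }
  rows <- lapply(segs, function(s) assemble_features(s, cond$fs, sensors))
  feats <- if (length(rows) > 0) {
    tibble::as_tibble(do.call(rbind, rows))
  } else {
    tibble::as_tibble(matrix(numeric(0), ncol = length(feature_names(sensors)),
                             dimnames = list(NULL, feature_names(sensors))))
  }
  dplyr::bind_cols(
    tibble::tibble(
      subject_id = rep(cond$subject_id, nrow(feats)),
      cycle = windows$index[seq_len(nrow(feats))],
      borg = if ("borg" %in% names(windows)) windows$borg[seq_len(nrow(feats))] else NA_real_,
      state = meta_state[seq_len(nrow(feats))]
    ),
    feats
  )
}

#' Normalize features to each subject's first repetition
#'
#' Inter-subject comparability of the time-amplitude features is obtained by
#' dividing every value by the same subject's first-cycle value (`fn = fi /
#' f0`), so each trajectory starts at 1 and expresses relative change.
#' Frequency-domain features (all MNF, MDF and IMNF columns) are already
#' comparable across subjects and pass through unchanged; the cycle duration
#' `FIB_tnorm` is normalized like the other time-amplitude features.
#'
#' @param table feature tibble (possibly several subjects) with `subject_id`
#'   and `cycle` columns.
#' @return the table with non-frequency feature columns divided by the
#'   per-subject first-cycle value. Errors, naming the feature, if any
#'   subject's first-cycle value is exactly zero.
#' @export
normalize_features <- function(table) {
  feat_cols <- intersect(feature_names(), names(table))
  if (length(feat_cols) == 0L) stop("no feature columns found")
  freq_cols <- grep("_(MNF|MDF|IMNF)$", feat_cols, value = TRUE)
  norm_cols <- setdiff(feat_cols, freq_cols)
  parts <- split(table, table$subject_id)
  parts <- lapply(parts, function(d) {
    d <- d[order(d$cycle), , drop = FALSE]
    f0 <- as.numeric(d[1L, norm_cols])
    zero <- norm_cols[f0 == 0]
    if (length(zero) > 0) {
      stop("first-cycle value is zero for feature(s): ",
           paste(zero, collapse = ", "), " (subject ", d$subject_id[1L], ")")
    }
    d[norm_cols] <- sweep(as.matrix(d[norm_cols]), 2L, f0, "/")
    d
  })
  dplyr::bind_rows(parts)
}
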