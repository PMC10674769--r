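#' Parameters of the synthetic fatigue cohort
#'
#' Bundles every knob of the simulator that emulates a repetitive biceps-curl
#' trial driven to exhaustion: a subject flexes and extends the elbow under
#' load while an optical-fiber sensor (OFS) tracks the elbow angle, a surface
#' EMG electrode records biceps activity, and two 6-channel inertial units
#' (wrist and neck) record movement. As the latent fatigue level rises,
#' repetitions slow, the range of motion (ROM) shrinks, the EMG envelope
#' grows while its spectral content compresses towards lower frequencies, and
#' compensatory neck movement appears. Perceived exertion is queried on the
#' Borg CR10 scale at a fixed interval and the trial stops at the first
#' rating of 10.
#'
#' Defaults describe the study conditions the analysis assumes: 30 subjects,
#' EMG sampled at 1024 Hz, IMUs at 128 Hz, Borg queried every 20 s, EMG
#' envelope rising from about 3 to 8 %MVC over the trial, and roughly 40
#' repetitions per subject.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param trial_duration_max hard safety cap on trial length (s).
#' @param time_to_exhaustion nominal time at which the latent Borg ramp
#'   reaches 10 (s); perturbed per subject.
#' @param base_cycle_period unfatigued repetition period (s).
#' @param cycle_slowing_rate relative period growth per unit fatigue
#'   (1 = period doubles at full fatigue).
#' @param rom_initial unfatigued elbow range of motion (degrees).
#' @param rom_decay ROM loss per unit fatigue (degrees).
#' @param emg_amp_initial unfatigued EMG envelope level (%MVC).
#' @param emg_amp_slope envelope growth per unit fatigue (%MVC).
#' @param emg_center_freq_initial unfatigued EMG spectral center (Hz).
#' @param emg_freq_compression downward drift of the EMG spectral center per
#'   unit fatigue (Hz).
#' @param emg_bandwidth two-sided bandwidth of the synthetic EMG band (Hz).
#' @param neck_compensation_gain amplitude scale of fatigue-driven neck
#'   movement (dimensionless; channel units at full fatigue are this gain
#'   times fixed per-channel factors).
#' @param noise_sd named list of additive sensor noise standard deviations:
#'   `ofs` (V), `emg` (mV), `imu_acc` (m/s^2), `imu_gyro` (deg/s).
#' @param borg_query_interval Borg CR10 query interval (s).
#' @param fs_ofs,fs_emg,fs_imu sampling rates (Hz).
#' @param mvc_value nominal maximum-voluntary-contraction envelope level (mV).
#' @param ofs_v_flex0,ofs_v_ext140 OFS calibration voltages at full flexion
#'   (0 deg) and extension (140 deg).
#' @param subject_sigma log-normal sigma of per-subject parameter
#'   perturbations.
#' @param seed default cohort seed.
#' @return a `synthetic_params` list, validated.
#' @export
synthetic_params <- function(n_subjects = 30L,
                             trial_duration_max = 600,
                             time_to_exhaustion = 200,
                             base_cycle_period = 4,
                             cycle_slowing_rate = 0.5,
                             rom_initial = 120,
                             rom_decay = 30,
                             emg_amp_initial = 3,
                             emg_amp_slope = 5,
                             emg_center_freq_initial = 90,
                             emg_freq_compression = 25,
                             emg_bandwidth = 80,
                             neck_compensation_gain = 1,
                             noise_sd = list(ofs = 0.01, emg = 0.005,
                                             imu_acc = 0.05, imu_gyro = 0.5),
                             borg_query_interval = 20,
                             fs_ofs = 100,
                             fs_emg = 1024,
                             fs_imu = 128,
                             mvc_value = 1,
                             ofs_v_flex0 = 2,
                             ofs_v_ext140 = 1,
                             subject_sigma = 0.08,
                             seed = 1L) {
  p <- list(
    n_subjects = as.integer(n_subjects),
    trial_duration_max = trial_duration_max,
    time_to_exhaustion = time_to_exhaustion,
    base_cycle_period = base_cycle_period,
    cycle_slowing_rate = cycle_slowing_rate,
    rom_initial = rom_initial,
    rom_decay = rom_decay,
    emg_amp_initial = emg_amp_initial,
    emg_amp_slope = emg_amp_slope,
    emg_center_freq_initial = emg_center_freq_initial,
    emg_freq_compression = emg_freq_compression,
    emg_bandwidth = emg_bandwidth,
    neck_compensation_gain = neck_compensation_gain,
    noise_sd = noise_sd,
    borg_query_interval = borg_query_interval,
    fs_ofs = fs_ofs,
    fs_emg = fs_emg,
    fs_imu = fs_imu,
    mvc_value = mvc_value,
    ofs_v_flex0 = ofs_v_flex0,
    ofs_v_ext140 = ofs_v_ext140,
    subject_sigma = subject_sigma,
    seed = as.integer(seed)
  )
  positive <- c(
    "trial_duration_max", "time_to_exhaustion", "base_cycle_period",
    "rom_initial", "emg_amp_initial", "emg_center_freq_initial",
    "emg_bandwidth", "borg_query_interval", "fs_ofs", "fs_emg", "fs_imu",
    "mvc_value"
  )
  for (nm in positive) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0) {
      stop("parameter '", nm, "' must be a positive scalar")
    }
  }
  if (p$emg_center_freq_initial >= p$fs_emg / 2) {
    stop("emg_center_freq_initial must lie below the EMG Nyquist frequency")
  }
  if (p$ofs_v_flex0 == p$ofs_v_ext140) {
    stop("OFS calibration voltages must differ")
  }
  structure(p, class = "synthetic_params")
}

# Latent perceived-exertion ramp: a monotone power ramp reaching 9 at 80% of
# the exhaustion time, then a slow plateau 9 -> 10 (most subjects linger near
# 9 before task failure). Exponent 1.4 makes the three fatigue states occupy
# roughly the shares observed in real exhaustion trials (~37/28/36%).
borg_latent <- function(t, t_exhaust) {
  t9 <- 0.8 * t_exhaust
  r <- ifelse(t <= t9,
    9 * (pmax(t, 0) / t9)^1.4,
    9 + (t - t9) / (0.2 * t_exhaust)
  )
  pmin(r, 10)
}

# Snap a latent rating to the CR10 response grid {0, 0.5, 1, 2, ..., 10}.
round_cr10 <- function(r) {
  grid <- c(0, 0.5, 1:10)
  grid[vapply(r, function(v) which.min(abs(grid - v)), integer(1))]
}

#' Borg CR10 trajectory of a synthetic subject
#'
#' Perceived exertion as a function of time: a monotone saturating ramp from
#' 0 at trial start to 10 at exhaustion with a plateau near 9, snapped to the
#' CR10 response grid (0, 0.5, 1, 2, ..., 10).
#'
#' @param t time or vector of times (s), non-negative.
#' @param params a [synthetic_params()] object (uses `time_to_exhaustion`).
#' @param t_exhaust override of the exhaustion time (s).
#' @return ratings on the CR10 grid, same length as `t`.
#' @export
borg_trajectory <- function(t, params = synthetic_params(),
                            t_exhaust = params$time_to_exhaustion) {
  if (any(t < 0)) stop("time must be non-negative")
  round_cr10(borg_latent(t, t_exhaust))
}

# Narrowband Gaussian EMG surrogate: unit-variance low-pass noise modulated
# by a cosine carrier whose instantaneous frequency is fc(t). The spectral
# centroid tracks fc(t); bandwidth is set by the baseband low-pass.
synth_emg_carrier <- function(n, fs, fc_t, bandwidth) {
  lp <- signal::butter(4, min(0.9, (bandwidth / 2) / (fs / 2)), "low")
  bb <- zero_phase_filter(lp, stats::rnorm(n), pad = round(4 * fs / bandwidth))
  bb <- bb / stats::sd(bb)
  theta <- 2 * pi * cumsum(fc_t) / fs
  bb * cos(theta)
}

#' Generate one synthetic fatigue trial
#'
#' Simulates the raw multi-rate streams of a single subject performing
#' biceps curls to exhaustion. The latent fatigue level `u(t)` (the Borg ramp
#' scaled to `[0, 1]`) drives every fatigue effect: the repetition period
#' grows as `base_cycle_period * (1 + cycle_slowing_rate * u)`, the angular
#' excursion shrinks as `rom_initial - rom_decay * u` (extension stays pinned
#' at 140 deg, flexion becomes incomplete), the EMG envelope grows as
#' `emg_amp_initial + emg_amp_slope * u` %MVC while its spectral center falls
#' as `emg_center_freq_initial - emg_freq_compression * u`, and neck channels
#' gain oscillation amplitude proportional to `neck_compensation_gain * u`.
#' Borg events are emitted every `borg_query_interval` seconds and the trial
#' is truncated at the first rating of 10 (or at `trial_duration_max`).
#'
#' @param params a [synthetic_params()] object.
#' @param subject_id subject identifier stored in the trial.
#' @param seed integer seed; identical seeds give identical trials.
#' @param load_kg load metadata (kg).
#' @return a `sensor_trial` list: `ofs_voltage`, `emg`, `imu_wrist`,
#'   `imu_neck` (n x 6 matrices, columns GyroX..AccZ), `borg_events`
#'   (data.frame `time_s`, `rating`), `calibration`, sampling rates,
#'   `duration` (s) and metadata.
#' @export
generate_trial <- function(params = synthetic_params(), subject_id = "S01",
                           seed = params$seed, load_kg = 4.5) {
  stopifnot(inherits(params, "synthetic_params"))
  set.seed(as.integer(seed))
  t_ex <- params$time_to_exhaustion

  # Borg schedule and trial truncation at the first rating of 10.
  te <- seq(0, params$trial_duration_max, by = params$borg_query_interval)
  ratings <- borg_trajectory(te, params, t_ex)
  hit <- which(ratings >= 10)
  if (length(hit) > 0) {
    te <- te[seq_len(hit[1L])]
    ratings <- ratings[seq_len(hit[1L])]
  }
  duration <- te[length(te)]

  u_of <- function(t) borg_latent(t, t_ex) / 10
  phase_of <- function(t) {
    dt <- c(0, diff(t))
    period <- params$base_cycle_period * (1 + params$cycle_slowing_rate * u_of(t))
    cumsum(2 * pi * dt / period)
  }
  angle_of <- function(t) {
    rom <- pmax(5, params$rom_initial - params$rom_decay * u_of(t))
    140 - rom * (1 + cos(phase_of(t))) / 2
  }

  # Per-channel sensor biases; the anatomical-hold baseline records the
  # static part of each channel (bias plus gravity in the hold posture).
  ch <- c("GyroX", "GyroY", "GyroZ", "AccX", "AccY", "AccZ")
  bias_wrist <- stats::setNames(c(stats::rnorm(3, 0, 0.3), stats::rnorm(3, 0, 0.05)), ch)
  bias_neck <- stats::setNames(c(stats::rnorm(3, 0, 0.3), stats::rnorm(3, 0, 0.05)), ch)
  grav_wrist <- stats::setNames(c(0, 0, 0, 0, 9.81, 0), ch)
  grav_neck <- stats::setNames(c(0, 0, 0, 0, 0, 9.81), ch)

  # OFS stream.
  n_ofs <- floor(duration * params$fs_ofs) + 1L
  t_ofs <- (seq_len(n_ofs) - 1L) / params$fs_ofs
  angle <- angle_of(t_ofs)
  v0 <- params$ofs_v_flex0
  v140 <- params$ofs_v_ext140
  ofs_voltage <- v0 + (v140 - v0) * angle / 140 +
    stats::rnorm(n_ofs, 0, params$noise_sd$ofs)

  # EMG stream.
  n_emg <- floor(duration * params$fs_emg) + 1L
  t_emg <- (seq_len(n_emg) - 1L) / params$fs_emg
  u_e <- u_of(t_emg)
  fc_t <- params$emg_center_freq_initial - params$emg_freq_compression * u_e
  carrier <- synth_emg_carrier(n_emg, params$fs_emg, fc_t, params$emg_bandwidth)
  burst <- 0.35 + 0.65 * (1 - cos(phase_of(t_emg))) / 2
  amp_mv <- params$mvc_value * (params$emg_amp_initial + params$emg_amp_slope * u_e) / 100
  # 1.97 rescales the rectified mean of the modulated noise to the target
  # envelope level (1 / (sqrt(2/pi) * mean |cos|)).
  emg <- 1.97 * amp_mv * burst * carrier + stats::rnorm(n_emg, 0, params$noise_sd$emg)

  # IMU streams.
  n_imu <- floor(duration * params$fs_imu) + 1L
  t_imu <- (seq_len(n_imu) - 1L) / params$fs_imu
  u_i <- u_of(t_imu)
  phi_i <- phase_of(t_imu)
  ang_i <- angle_of(t_imu)
  omega <- c(0, diff(ang_i)) * params$fs_imu # deg/s
  alpha <- c(0, diff(omega)) * params$fs_imu # deg/s^2
  sd_a <- params$noise_sd$imu_acc
  sd_g <- params$noise_sd$imu_gyro
  nois <- function(s) stats::rnorm(n_imu, 0, s)
  imu_wrist <- cbind(
    GyroX = omega + bias_wrist["GyroX"] + nois(sd_g),
    GyroY = 0.3 * omega + bias_wrist["GyroY"] + nois(sd_g),
    GyroZ = 2 * u_i + bias_wrist["GyroZ"] + nois(sd_g),
    AccX = 9.81 * sin(ang_i * pi / 180) + bias_wrist["AccX"] + nois(sd_a),
    AccY = 9.81 * cos(ang_i * pi / 180) + bias_wrist["AccY"] + nois(sd_a),
    AccZ = (pi / 180 * 0.3) * alpha + bias_wrist["AccZ"] + nois(sd_a)
  )
  gain <- params$neck_compensation_gain * u_i
  imu_neck <- cbind(
    GyroX = 8 * gain * sin(phi_i) + bias_neck["GyroX"] + nois(sd_g),
    GyroY = 5 * gain * sin(phi_i + 1) + bias_neck["GyroY"] + nois(sd_g),
    GyroZ = 3 * gain * sin(phi_i + 2) + bias_neck["GyroZ"] + nois(sd_g),
    AccX = 0.6 * gain * sin(phi_i) + bias_neck["AccX"] + nois(sd_a),
    AccY = 0.4 * gain * sin(phi_i + 0.7) + bias_neck["AccY"] + nois(sd_a),
    AccZ = 9.81 + 0.3 * gain * sin(phi_i + 1.4) + bias_neck["AccZ"] + nois(sd_a)
  )

  calibration <- list(
    mvc_value = params$mvc_value * exp(stats::rnorm(1, 0, 0.02)),
    ofs_v_flex0 = v0,
    ofs_v_ext140 = v140,
    imu_baseline = list(
      wrist = bias_wrist + grav_wrist,
      neck = bias_neck + grav_neck
    )
  )

  structure(list(
    subject_id = subject_id,
    ofs_voltage = ofs_voltage,
    emg = emg,
    imu_wrist = imu_wrist,
    imu_neck = imu_neck,
    borg_events = data.frame(time_s = te, rating = ratings),
    calibration = calibration,
    fs = list(ofs = params$fs_ofs, emg = params$fs_emg, imu = params$fs_imu),
    duration = duration,
    load_kg = load_kg,
    seed = as.integer(seed),
    t_exhaust = t_ex
  ), class = "sensor_trial")
}

#' @export
print.sensor_trial <- function(x, ...) {
  cat(
    "<sensor_trial>", x$subject_id, "-", x$duration, "s,",
    nrow(x$borg_events), "Borg events (last rating",
    x$borg_events$rating[nrow(x$borg_events)], ")\n"
  )
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws `n_subjects` trials with per-subject log-normal perturbations of the
#' fatigue dynamics (period, slowing rate, ROM and its decay, EMG amplitude
#' and frequency parameters, neck gain, exhaustion time), so subjects differ
#' in pace, endurance and effect size, as a real cohort does.
#'
#' @param params a [synthetic_params()] object (`n_subjects >= 2`).
#' @param seed cohort seed driving the per-subject seeds and perturbations.
#' @return list with `trials` (list of `sensor_trial`), `manifest` (one row
#'   per trial: subject, seed, exhaustion time, duration, cycles of Borg
#'   events, load) and `params`.
#' @export
generate_cohort <- function(params = synthetic_params(), seed = params$seed) {
  stopifnot(inherits(params, "synthetic_params"))
  n <- params$n_subjects
  if (n < 2L) stop("need at least 2 subjects to form a train/test split")
  set.seed(as.integer(seed))
  subject_seeds <- sample.int(1e7L, n)
  perturb_fields <- c(
    "base_cycle_period", "cycle_slowing_rate", "rom_initial", "rom_decay",
    "emg_amp_initial", "emg_amp_slope", "emg_center_freq_initial",
    "emg_freq_compression", "neck_compensation_gain", "time_to_exhaustion"
  )
  factors <- matrix(
    exp(stats::rnorm(n * length(perturb_fields), 0, params$subject_sigma)),
    nrow = n, dimnames = list(NULL, perturb_fields)
  )
  load <- rep(c(2.5, 4.5), length.out = n)
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    p_i <- params
    for (f in perturb_fields) p_i[[f]] <- params[[f]] * factors[i, f]
    trials[[i]] <- generate_trial(
      p_i,
      subject_id = sprintf("S%02d", i),
      seed = subject_seeds[i],
      load_kg = load[i]
    )
  }
  manifest <- tibble::tibble(
    subject_id = vapply(trials, `[[`, "", "subject_id"),
    seed = subject_seeds,
    time_to_exhaustion = vapply(trials, `[[`, 0, "t_exhaust"),
    duration = vapply(trials, `[[`, 0, "duration"),
    n_borg_events = vapply(trials, function(tr) nrow(tr$borg_events), 0L),
    final_rating = vapply(
      trials,
      function(tr) tr$borg_events$rating[nrow(tr$borg_events)], 0
    ),
    load_kg = load
  )
  list(trials = trials, manifest = manifest, params = params,
       cohort_seed = as.integer(seed))
}

#' Write a cohort to disk in the per-subject CSV layout
#'
#' One directory per subject with `ofs.csv`, `emg.csv`, `imu_wrist.csv`,
#' `imu_neck.csv` (a `time_s` column plus channel columns), `borg.csv`
#' (`time_s,rating`) and `calibration.json`; the cohort root gets
#' `manifest.json` with seeds, rates and parameters.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in cohort$trials) {
    sdir <- file.path(dir, tr$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    n_ofs <- length(tr$ofs_voltage)
    data.table::fwrite(
      data.table::data.table(
        time_s = (seq_len(n_ofs) - 1L) / tr$fs$ofs,
        voltage = tr$ofs_voltage
      ),
      file.path(sdir, "ofs.csv")
    )
    n_emg <- length(tr$emg)
    data.table::fwrite(
      data.table::data.table(
        time_s = (seq_len(n_emg) - 1L) / tr$fs$emg,
        emg = tr$emg
      ),
      file.path(sdir, "emg.csv")
    )
    for (site in c("wrist", "neck")) {
      m <- tr[[paste0("imu_", site)]]
      data.table::fwrite(
        data.table::data.table(
          time_s = (seq_len(nrow(m)) - 1L) / tr$fs$imu,
          m
        ),
        file.path(sdir, paste0("imu_", site, ".csv"))
      )
    }
    data.table::fwrite(tr$borg_events, file.path(sdir, "borg.csv"))
    jsonlite::write_json(
      c(tr$calibration[c("mvc_value", "ofs_v_flex0", "ofs_v_ext140")],
        list(
          imu_baseline = lapply(tr$calibration$imu_baseline, as.list),
          fs = tr$fs, load_kg = tr$load_kg, seed = tr$seed
        )),
      file.path(sdir, "calibration.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  jsonlite::write_json(
    list(
      cohort_seed = cohort$cohort_seed,
      params = unclass(cohort$params),
      manifest = cohort$manifest
    ),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(dir)
}

#' Read one subject's trial back from the CSV layout
#'
#' @param sdir subject directory written by [write_cohort()].
#' @return a `sensor_trial`.
#' @export
read_trial <- function(sdir) {
  cal <- jsonlite::read_json(file.path(sdir, "calibration.json"),
                             simplifyVector = TRUE)
  ofs <- data.table::fread(file.path(sdir, "ofs.csv"))
  emg <- data.table::fread(file.path(sdir, "emg.csv"))
  borg <- data.table::fread(file.path(sdir, "borg.csv"))
  read_imu <- function(site) {
    m <- data.table::fread(file.path(sdir, paste0("imu_", site, ".csv")))
    as.matrix(m[, -1L])
  }
  structure(list(
    subject_id = basename(sdir),
    ofs_voltage = ofs$voltage,
    emg = emg$emg,
    imu_wrist = read_imu("wrist"),
    imu_neck = read_imu("neck"),
    borg_events = as.data.frame(borg),
    calibration = list(
      mvc_value = cal$mvc_value,
      ofs_v_flex0 = cal$ofs_v_flex0,
      ofs_v_ext140 = cal$ofs_v_ext140,
      imu_baseline = lapply(cal$imu_baseline, unlist)
    ),
    fs = cal$fs,
    duration = borg$time_s[nrow(borg)],
    load_kg = cal$load_kg,
    seed = cal$seed,
    t_exhaust = NA_real_
  ), class = "sensor_trial")
}
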