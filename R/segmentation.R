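#' Interpolate Borg CR10 events over time
#'
#' Piecewise-linear interpolation of the discrete Borg queries, so every
#' instant of the trial carries a graded exertion value; before the first
#' event the first rating holds, after the last event the last rating holds.
#'
#' @param events data.frame with strictly increasing `time_s` and `rating`.
#' @param query_times times (s) at which to evaluate.
#' @return interpolated ratings, same length as `query_times`.
#' @export
interpolate_borg <- function(events, query_times) {
  if (is.null(events) || nrow(events) == 0L) stop("no Borg events to interpolate")
  if (nrow(events) > 1L && any(diff(events$time_s) <= 0)) {
    stop("Borg event times must be strictly increasing")
  }
  if (nrow(events) == 1L) {
    return(rep(events$rating[1L], length(query_times)))
  }
  stats::approx(events$time_s, events$rating, xout = query_times,
                rule = 2, ties = "ordered")$y
}

# Dominant-period estimate in samples: first local maximum of the
# autocorrelation after its first zero crossing; spectral peak as fallback.
estimate_period <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  ac <- stats::acf(x, lag.max = min(n - 1L, 5000L), plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  neg <- which(ac < 0)
  if (length(neg) > 0) {
    tail_ac <- ac[neg[1L]:length(ac)]
    d <- diff(tail_ac)
    pk <- which(d[-length(d)] > 0 & d[-1L] <= 0)
    if (length(pk) > 0) {
      return(neg[1L] + pk[1L]) # lag of the first autocorrelation peak
    }
  }
  # fallback: periodogram argmax
  spec <- Mod(stats::fft(x))^2
  half <- 2:(floor(n / 2) + 1L)
  k <- half[which.max(spec[half])] - 1L
  max(2L, round(n / k))
}

# Topographic prominence of each local maximum: height above the higher of
# the two valley floors separating it from the nearest higher terrain.
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    left_min <- Inf
    i <- p - 1L
    lm <- x[p]
    while (i >= 1L && x[i] <= x[p]) {
      lm <- min(lm, x[i])
      i <- i - 1L
    }
    left_min <- if (i >= 1L) lm else min(lm, min(x[1:p]))
    right_min <- Inf
    i <- p + 1L
    rm_ <- x[p]
    while (i <= length(x) && x[i] <= x[p]) {
      rm_ <- min(rm_, x[i])
      i <- i + 1L
    }
    right_min <- if (i <= length(x)) rm_ else min(rm_, min(x[p:length(x)]))
    x[p] - max(left_min, right_min)
  }, numeric(1))
}

#' Detect biceps-curl repetition cycles from the elbow-angle signal
#'
#' Locates the maxima of the filtered angle (full-extension peaks) and
#' defines each repetition window as the span between consecutive peaks, so
#' `n` peaks yield `n - 1` variable-length, non-overlapping windows. Peak
#' acceptance is scale-free: minimum prominence is a fraction of the signal
#' range and minimum separation a fraction of the autocorrelation-estimated
#' cycle period, which keeps detection robust as fatigue shrinks the range of
#' motion and stretches the period.
#'
#' @param angle an `angle_series` (filtered).
#' @param min_prominence_frac minimum peak prominence as a fraction of the
#'   signal range.
#' @param min_separation_frac minimum peak separation as a fraction of the
#'   estimated cycle period.
#' @return tibble of windows: `index`, `t_start`, `t_end`, `duration` (s);
#'   zero rows (with a warning) when fewer than two peaks exist.
#' @export
detect_cycles <- function(angle, min_prominence_frac = 0.2,
                          min_separation_frac = 0.5) {
  stopifnot(inherits(angle, "angle_series"))
  x <- angle$angle
  empty <- tibble::tibble(
    index = integer(), t_start = numeric(),
    t_end = numeric(), duration = numeric()
  )
  rng <- diff(range(x))
  if (length(x) < 3L || rng == 0) {
    warning("fewer than 2 peaks found; no cycles detected")
    return(empty)
  }
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (length(cand) > 0) {
    prom <- peak_prominence(x, cand)
    cand <- cand[prom >= min_prominence_frac * rng]
  }
  if (length(cand) >= 2L) {
    min_sep <- min_separation_frac * estimate_period(x)
    keep <- logical(length(cand))
    taken <- integer(0)
    for (j in order(x[cand], decreasing = TRUE)) {
      if (all(abs(cand[j] - taken) >= min_sep)) {
        keep[j] <- TRUE
        taken <- c(taken, cand[j])
      }
    }
    cand <- sort(cand[keep])
  }
  if (length(cand) < 2L) {
    warning("fewer than 2 peaks found; no cycles detected")
    return(empty)
  }
  t_pk <- angle$time[cand]
  tibble::tibble(
    index = seq_len(length(cand) - 1L),
    t_start = t_pk[-length(t_pk)],
    t_end = t_pk[-1L],
    duration = diff(t_pk)
  )
}

#' Fatigue-state boundaries on the Borg CR10 scale
#'
#' Low fatigue (LF) covers ratings up to `lf_max`, moderate (MOF) up to
#' `mof_max`, and high (HF) everything above up to 10. The defaults (3 and 6)
#' follow the CR10 verbal anchors ("moderate" near 3, "very strong" near 7)
#' and are configurable.
#'
#' @param lf_max upper rating of the low-fatigue state.
#' @param mof_max upper rating of the moderate-fatigue state.
#' @return a `state_boundaries` list.
#' @export
state_boundaries <- function(lf_max = 3, mof_max = 6) {
  if (!(lf_max >= 0 && lf_max < mof_max && mof_max < 10)) {
    stop("boundaries must satisfy 0 <= lf_max < mof_max < 10")
  }
  structure(list(lf_max = lf_max, mof_max = mof_max),
            class = "state_boundaries")
}

#' Canonical fatigue-state labels
#' @return factor levels, in ordinal order.
#' @export
fatigue_states <- function() c("LF", "MOF", "HF")

#' Map a Borg rating to a fatigue state
#'
#' @param borg rating(s) in `[0, 10]`.
#' @param bounds a [state_boundaries()] object.
#' @return factor with levels LF, MOF, HF.
#' @export
assign_state <- function(borg, bounds = state_boundaries()) {
  if (any(borg < 0 | borg > 10)) stop("Borg rating out of [0, 10]")
  out <- ifelse(borg <= bounds$lf_max, "LF",
                ifelse(borg <= bounds$mof_max, "MOF", "HF"))
  factor(out, levels = fatigue_states())
}

#' Label repetition windows with interpolated Borg and fatigue state
#'
#' Each window receives the interpolated Borg value at its midpoint and the
#' corresponding state.
#'
#' @param windows window tibble from [detect_cycles()].
#' @param events Borg events (`time_s`, `rating`).
#' @param bounds a [state_boundaries()] object.
#' @return the window tibble with `borg` and `state` columns added.
#' @export
label_cycles <- function(windows, events, bounds = state_boundaries()) {
  if (nrow(windows) == 0L) {
    windows$borg <- numeric()
    windows$state <- factor(character(), levels = fatigue_states())
    return(windows)
  }
  mid <- (windows$t_start + windows$t_end) / 2
  windows$borg <- interpolate_borg(events, mid)
  windows$state <- assign_state(windows$borg, bounds)
  windows
}

#' Slice all conditioned streams by repetition window
#'
#' The cycle boundaries detected on the angle signal are the time reference
#' for every sensor: each stream is cut at its native rate on the half-open
#' interval `[t_start, t_end)`, so no sample belongs to two windows.
#'
#' @param cond a `conditioned_trial`.
#' @param windows labeled window tibble.
#' @return list with one element per window: `index`, `t_start`, `t_end`,
#'   `duration`, `borg`, `state`, `angle`, `emg_bandpassed`, `emg_envelope`,
#'   `imu_wrist`, `imu_neck`.
#' @export
slice_streams <- function(cond, windows) {
  stopifnot(inherits(cond, "conditioned_trial"))
  if (nrow(windows) == 0L) return(list())
  if (any(windows$t_start < 0) || any(windows$t_end > cond$duration + 1e-9)) {
    stop("window extends outside the recording")
  }
  cut_idx <- function(n, rate, t0, t1) {
    # half-open [t0, t1): samples k/rate with k in [ceil(t0*rate), t1*rate)
    i0 <- ceiling(t0 * rate - 1e-9) + 1L
    i1 <- floor(t1 * rate - 1e-9) + 1L
    if (i1 < i0) integer(0) else i0:min(i1, n)
  }
  lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    ia <- cut_idx(length(cond$angle$angle), cond$fs$ofs, w$t_start, w$t_end)
    ie <- cut_idx(length(cond$emg$bandpassed), cond$fs$emg, w$t_start, w$t_end)
    ii <- cut_idx(nrow(cond$imu_wrist), cond$fs$imu, w$t_start, w$t_end)
    list(
      index = w$index, t_start = w$t_start, t_end = w$t_end,
      duration = w$duration,
      borg = if ("borg" %in% names(w)) w$borg else NA_real_,
      state = if ("state" %in% names(w)) w$state else NA,
      angle = cond$angle$angle[ia],
      emg_bandpassed = cond$emg$bandpassed[ie],
      emg_envelope = cond$emg$envelope_pct_mvc[ie],
      imu_wrist = cond$imu_wrist[ii, , drop = FALSE],
      imu_neck = cond$imu_neck[ii, , drop = FALSE]
    )
  })
}
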