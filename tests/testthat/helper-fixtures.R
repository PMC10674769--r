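# Shared fixtures, generated in code.

# Small, fast trial parameters: short exhaustion, fewer subjects.
tiny_params <- function(n_subjects = 3L, time_to_exhaustion = 80, ...) {
  synthetic_params(
    n_subjects = n_subjects,
    time_to_exhaustion = time_to_exhaustion,
    ...
  )
}

# One small conditioned trial with labeled windows, cached per session.
.fixture_env <- new.env(parent = emptyenv())

tiny_conditioned <- function() {
  if (is.null(.fixture_env$cond)) {
    tr <- generate_trial(tiny_params(), subject_id = "S01", seed = 42)
    cond <- condition_trial(tr)
    windows <- label_cycles(detect_cycles(cond$angle), cond$borg_events)
    .fixture_env$cond <- list(trial = tr, cond = cond, windows = windows)
  }
  .fixture_env$cond
}

# Fabricated feature table: n_subj subjects x n_cycles cycles with the full
# canonical feature catalog; a handful of columns carry the state signal,
# the rest are noise. Used by model-layer tests that do not need signals.
toy_features <- function(n_subj = 6L, n_cycles = 21L, seed = 99L) {
  set.seed(seed)
  nm <- feature_names()
  rows <- n_subj * n_cycles
  m <- matrix(rnorm(rows * length(nm)), rows, dimnames = list(NULL, nm))
  cycle <- rep(seq_len(n_cycles), n_subj)
  u <- (cycle - 1) / (n_cycles - 1)
  m[, "EMG_mean"] <- 1 + 5 * u + rnorm(rows, 0, 0.2)
  m[, "EMG_IMNF"] <- 90 - 25 * u + rnorm(rows, 0, 1)
  m[, "FIB_tnorm"] <- 1 + 0.5 * u + rnorm(rows, 0, 0.05)
  m[, "IMU1_AccX_std"] <- 2 + 3 * u + rnorm(rows, 0, 0.2)
  state <- assign_state(round(10 * u) )
  dplyr::bind_cols(
    tibble::tibble(
      subject_id = rep(sprintf("S%02d", seq_len(n_subj)), each = n_cycles),
      cycle = cycle,
      borg = 10 * u,
      state = state
    ),
    tibble::as_tibble(m)
  )
}

# Full-size pipeline run under the default study conditions, computed once
# and shared by the acceptance tests.
acceptance_run <- function() {
  if (is.null(.fixture_env$run)) {
    .fixture_env$run <- run_pipeline(synthetic_params(), seed = 1L)
  }
  .fixture_env$run
}

make_angle_series <- function(angle, rate) {
  structure(
    list(time = (seq_along(angle) - 1L) / rate, angle = angle, rate = rate),
    class = "angle_series"
  )
}
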