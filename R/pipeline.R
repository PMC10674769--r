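#' Per-cycle feature table of a whole cohort
#'
#' Conditions every trial, segments repetition cycles from the elbow angle,
#' labels them with interpolated Borg states, and extracts the canonical
#' feature catalog.
#'
#' @param cohort result of [generate_cohort()] (or a list with `trials`).
#' @param bounds fatigue-state boundaries.
#' @param sensors sensors to extract.
#' @return unnormalized feature tibble over all subjects.
#' @export
cohort_features <- function(cohort, bounds = state_boundaries(),
                            sensors = c("imu1", "imu2", "ofs", "emg")) {
  tabs <- lapply(cohort$trials, function(tr) {
    cond <- condition_trial(tr)
    windows <- label_cycles(detect_cycles(cond$angle), cond$borg_events, bounds)
    extract_trial_features(cond, windows, sensors)
  })
  dplyr::bind_rows(tabs)
}

#' Per-subject trend directions of the core fatigue effects
#'
#' For each subject, fits a least-squares line of the per-cycle EMG envelope
#' mean, EMG instantaneous mean frequency, cycle duration, and range of
#' motion against cycle index, and reports the slope signs. On fatiguing
#' trials the expected directions are: envelope up, IMNF down, duration up,
#' ROM down.
#'
#' @param features unnormalized feature tibble.
#' @return tibble with one row per subject: slopes and a `recovered` flag
#'   (all four directions correct).
#' @export
trend_directions <- function(features) {
  slope <- function(y, x) {
    if (length(y) < 3L) return(NA_real_)
    stats::cov(x, y) / stats::var(x)
  }
  parts <- split(features, features$subject_id)
  rows <- lapply(parts, function(d) {
    d <- d[order(d$cycle), , drop = FALSE]
    x <- d$cycle
    tibble::tibble(
      subject_id = d$subject_id[1L],
      emg_mean_slope = slope(d$EMG_mean, x),
      emg_imnf_slope = slope(d$EMG_IMNF, x),
      duration_slope = slope(d$FIB_tnorm, x),
      rom_slope = slope(d$FIB_ROM, x)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$recovered <- out$emg_mean_slope > 0 & out$emg_imnf_slope < 0 &
    out$duration_slope > 0 & out$rom_slope < 0
  out
}

#' Run the full fatigue-estimation pipeline on a synthetic cohort
#'
#' Generates the cohort, extracts and normalizes per-cycle features, splits
#' subjects 70:30, tunes the gradient-boosted classifier by
#' leave-one-subject-out cross-validation, ranks split importance, and runs
#' the sensor-ablation protocol.
#'
#' @param params a [synthetic_params()] object.
#' @param seed master seed (drives cohort generation, split and training).
#' @param family classifier family for the tuned model.
#' @param grid hyperparameter grid.
#' @param combos sensor combinations to ablate.
#' @param combo_k per-combo feature budgets.
#' @param bounds fatigue-state boundaries.
#' @return list: `cohort` (manifest only), `features` (normalized), `plan`,
#'   `cv`, `fit`, `importance`, `reports` (per-combo), `trends`.
#' @export
run_pipeline <- function(params = synthetic_params(), seed = 1L,
                         family = "lgbm", grid = default_grid(family),
                         combos = names(sensor_combos()),
                         combo_k = default_combo_k(),
                         bounds = state_boundaries()) {
  cohort <- generate_cohort(params, seed = seed)
  raw <- cohort_features(cohort, bounds)
  feats <- normalize_features(raw)
  plan <- split_dataset(unique(feats$subject_id), ratio = 0.7, seed = seed)
  cv <- loocv_grid_search(feats, plan, family = family, grid = grid,
                          seed = seed)
  train_tbl <- feats[feats$subject_id %in% plan$train_subjects, , drop = FALSE]
  fit <- train_classifier(feature_matrix(train_tbl), train_tbl$state,
                          family, cv$best_params, seed = seed)
  importance <- if (family == "lgbm") rank_importance(fit) else NULL
  gbt_params <- if (family == "lgbm") cv$best_params else
    default_grid("lgbm")[nrow(default_grid("lgbm")), , drop = FALSE]
  reports <- ablate_sensors(feats, plan, combos = combos, k = combo_k,
                            params = gbt_params, seed = seed)
  list(
    cohort = cohort["manifest"],
    features = feats,
    raw_features = raw,
    plan = plan,
    cv = cv,
    fit = fit,
    importance = importance,
    reports = reports,
    trends = trend_directions(raw)
  )
}
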