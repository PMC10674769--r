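#' Subject-wise train/test split
#'
#' Partitions subjects (never individual cycles) into a training and a test
#' group, so every cycle of a subject lies on one side only — the guard
#' against within-subject leakage that inflates cross-validated accuracy.
#'
#' @param subject_ids vector of subject identifiers.
#' @param ratio training fraction; `round(ratio * n)` subjects train.
#' @param seed split seed.
#' @return a `split_plan` list: `train_subjects`, `test_subjects`, `ratio`,
#'   `seed`.
#' @export
split_dataset <- function(subject_ids, ratio = 0.7, seed = 1L) {
  ids <- unique(as.character(subject_ids))
  n <- length(ids)
  if (n < 2L) stop("need at least 2 subjects to split")
  if (!(ratio > 0 && ratio < 1)) stop("ratio must lie in (0, 1)")
  n_train <- round(ratio * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  set.seed(as.integer(seed))
  train <- sort(sample(ids, n_train))
  structure(list(
    train_subjects = train,
    test_subjects = sort(setdiff(ids, train)),
    ratio = ratio,
    seed = as.integer(seed)
  ), class = "split_plan")
}

#' Default hyperparameter grids
#'
#' Small neighborhoods around well-performing settings for each of the five
#' retained tree-ensemble families: gradient-boosted trees (`lgbm`; leaf-wise
#' growth with `num_leaves` up to 181 and `min_child_samples` 8), random
#' forest (`rf`; up to 1400 trees, depth 40, no bootstrap resampling option
#' exposed), bagged trees (`bc`; 10 deep trees on 70% feature draws),
#' extremely randomized trees (`et`; 200 trees) and a single decision tree
#' (`dt`; gini, minimum leaf size 1).
#'
#' @param family one of `"lgbm"`, `"rf"`, `"bc"`, `"et"`, `"dt"`.
#' @return data.frame, one row per candidate.
#' @export
default_grid <- function(family = c("lgbm", "rf", "bc", "et", "dt")) {
  family <- match.arg(family)
  switch(family,
    lgbm = expand.grid(
      num_leaves = c(31, 181), min_child_samples = 8,
      learning_rate = 0.1, n_estimators = 100
    ),
    rf = expand.grid(num_trees = c(500, 1400), max_depth = 40),
    bc = expand.grid(num_trees = 10, max_depth = 20, max_features = 0.7),
    et = expand.grid(num_trees = 200, max_depth = 0),
    dt = expand.grid(min_samples_split = c(2, 8), min_samples_leaf = 1)
  )
}

#' Extract the numeric feature matrix from a feature tibble
#'
#' @param table feature tibble (metadata columns are ignored).
#' @param features optional subset/order of feature columns.
#' @return numeric matrix with feature column names.
#' @export
feature_matrix <- function(table, features = NULL) {
  cols <- intersect(feature_names(), names(table))
  if (!is.null(features)) {
    missing <- setdiff(features, cols)
    if (length(missing) > 0) {
      stop("feature(s) not present in table: ", paste(missing, collapse = ", "))
    }
    cols <- features
  }
  as.matrix(table[cols])
}

#' Train one classifier family on a feature matrix
#'
#' @param x numeric feature matrix with column names.
#' @param y factor of fatigue states (levels LF, MOF, HF).
#' @param family model family (see [default_grid()]).
#' @param params one-row data.frame (or list) of hyperparameters.
#' @param seed training seed.
#' @return a `fatigue_model` list: `model`, `family`, `features`, `levels`,
#'   `params`.
#' @export
train_classifier <- function(x, y, family = "lgbm",
                             params = default_grid(family)[1L, , drop = FALSE],
                             seed = 1L) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  y <- factor(y, levels = fatigue_states())
  params <- as.list(params)
  set.seed(as.integer(seed))
  model <- switch(family,
    lgbm = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      xgboost::xgb.train(
        params = list(
          objective = "multi:softprob", num_class = 3L,
          tree_method = "hist", grow_policy = "lossguide",
          max_depth = 0L, max_leaves = params$num_leaves,
          min_child_weight = params$min_child_samples,
          eta = params$learning_rate, nthread = 1L
        ),
        data = dtrain, nrounds = params$n_estimators, verbose = 0
      )
    },
    rf = ranger::ranger(
      x = x, y = y, num.trees = params$num_trees,
      max.depth = params$max_depth, seed = as.integer(seed),
      num.threads = 1L
    ),
    bc = ranger::ranger(
      x = x, y = y, num.trees = params$num_trees,
      max.depth = params$max_depth,
      mtry = max(1L, floor(params$max_features * ncol(x))),
      seed = as.integer(seed), num.threads = 1L
    ),
    et = ranger::ranger(
      x = x, y = y, num.trees = params$num_trees,
      splitrule = "extratrees", num.random.splits = 1L,
      max.depth = params$max_depth, seed = as.integer(seed),
      num.threads = 1L
    ),
    dt = rpart::rpart(
      state ~ ., data = data.frame(state = y, x, check.names = FALSE),
      method = "class",
      control = rpart::rpart.control(
        minsplit = params$min_samples_split,
        minbucket = params$min_samples_leaf, cp = 0, xval = 0
      ),
      parms = list(split = "gini")
    ),
    stop("unknown model family: ", family)
  )
  structure(list(
    model = model, family = family, features = colnames(x),
    levels = fatigue_states(), params = params
  ), class = "fatigue_model")
}

#' Predict fatigue states
#'
#' @param fit a `fatigue_model`.
#' @param x feature matrix with the model's feature columns.
#' @return factor of predicted states.
#' @export
predict_states <- function(fit, x) {
  stopifnot(inherits(fit, "fatigue_model"))
  missing <- setdiff(fit$features, colnames(x))
  if (length(missing) > 0) {
    stop("feature(s) missing from prediction matrix: ",
         paste(missing, collapse = ", "))
  }
  x <- x[, fit$features, drop = FALSE]
  idx <- switch(fit$family,
    lgbm = {
      p <- predict(fit$model, xgboost::xgb.DMatrix(x))
      max.col(matrix(p, ncol = 3L, byrow = FALSE))
    },
    dt = max.col(predict(fit$model, data.frame(x, check.names = FALSE),
                         type = "prob")),
    # ranger families
    as.integer(predict(fit$model, data = x,
                       num.threads = 1L)$predictions)
  )
  factor(fit$levels[idx], levels = fit$levels)
}

#' Leave-one-subject-out cross-validated grid search
#'
#' For every hyperparameter candidate, trains once per training subject with
#' that subject's cycles held out (folds = number of training subjects) and
#' scores held-out accuracy; the candidate with the best mean fold accuracy
#' wins, ties broken by weighted F1 and then by grid order. All candidates
#' share the same folds.
#'
#' @param table normalized feature tibble with `subject_id` and `state`.
#' @param plan a [split_dataset()] plan; only its training subjects are used.
#' @param family model family.
#' @param grid candidate data.frame (see [default_grid()]).
#' @param seed training seed.
#' @return list: `best_params` (one-row data.frame), `cv_results` (tibble of
#'   per-candidate mean accuracy/F1), `fold_subjects`, `family`.
#' @export
loocv_grid_search <- function(table, plan, family = "lgbm",
                              grid = default_grid(family), seed = 1L) {
  stopifnot(inherits(plan, "split_plan"))
  if (nrow(grid) == 0L) stop("hyperparameter grid is empty")
  train_tbl <- table[table$subject_id %in% plan$train_subjects, , drop = FALSE]
  folds <- sort(unique(train_tbl$subject_id))
  if (length(folds) < 2L) stop("need at least 2 training subjects for LOOCV")
  acc <- matrix(NA_real_, nrow(grid), length(folds))
  f1 <- matrix(NA_real_, nrow(grid), length(folds))
  for (g in seq_len(nrow(grid))) {
    for (k in seq_along(folds)) {
      held <- folds[k]
      tr <- train_tbl[train_tbl$subject_id != held, , drop = FALSE]
      va <- train_tbl[train_tbl$subject_id == held, , drop = FALSE]
      if (length(unique(tr$state)) < 2L) {
        warning("fold ", held, " skipped: single-class training data")
        next
      }
      fit <- train_classifier(feature_matrix(tr), tr$state, family,
                              grid[g, , drop = FALSE], seed = seed)
      pred <- predict_states(fit, feature_matrix(va))
      cm <- confusion(va$state, pred)
      acc[g, k] <- sum(diag(cm)) / sum(cm)
      f1[g, k] <- metrics(cm, "weighted")[["f1"]]
    }
  }
  cv_results <- tibble::tibble(
    candidate = seq_len(nrow(grid)),
    grid,
    cv_accuracy = rowMeans(acc, na.rm = TRUE),
    cv_f1 = rowMeans(f1, na.rm = TRUE)
  )
  best <- order(-cv_results$cv_accuracy, -cv_results$cv_f1,
                cv_results$candidate)[1L]
  list(
    best_params = grid[best, , drop = FALSE],
    cv_results = cv_results,
    fold_subjects = folds,
    family = family
  )
}

#' Split-importance ranking of a gradient-boosted model
#'
#' Counts how many times each feature is used as a split across all trees of
#' the boosted ensemble (split importance), and ranks features by that
#' count; ties keep the model's canonical feature order. Features the
#' ensemble never splits on receive count 0.
#'
#' @param fit a `fatigue_model` of family `"lgbm"`.
#' @return tibble `feature`, `splits`, sorted by nonincreasing count.
#' @export
rank_importance <- function(fit) {
  stopifnot(inherits(fit, "fatigue_model"))
  if (fit$family != "lgbm") {
    stop("split importance is defined for the gradient-boosted model only")
  }
  tree_tbl <- xgboost::xgb.model.dt.tree(model = fit$model)
  used <- tree_tbl$Feature[tree_tbl$Feature != "Leaf"]
  counts <- table(factor(used, levels = fit$features))
  ord <- order(-as.integer(counts), seq_along(fit$features))
  tibble::tibble(
    feature = fit$features[ord],
    splits = as.integer(counts)[ord]
  )
}

#' Select the top-k features of a ranking
#'
#' @param ranking tibble from [rank_importance()].
#' @param k number of features, `1 <= k <= nrow(ranking)`.
#' @return character vector of the first `k` feature names.
#' @export
select_top_features <- function(ranking, k) {
  if (k < 1L || k > nrow(ranking)) {
    stop("k must lie in [1, ", nrow(ranking), "]")
  }
  ranking$feature[seq_len(k)]
}

#' Sensor combinations of the ablation protocol
#'
#' @return named list mapping combination labels to sensor sets.
#' @export
sensor_combos <- function() {
  list(
    emg = "emg",
    ofs = "ofs",
    imu1 = "imu1",
    imu2 = "imu2",
    imus = c("imu1", "imu2"),
    imus_ofs = c("imu1", "imu2", "ofs"),
    all = c("imu1", "imu2", "ofs", "emg")
  )
}

#' Default feature budgets per sensor combination
#'
#' The number of top-ranked features retained when each combination is
#' retrained: 7 (EMG), 8 (OFS), 5 (wrist IMU), 4 (neck IMU), 10 (both IMUs),
#' 13 (IMUs + OFS), 33 (all sensors).
#'
#' @return named integer vector.
#' @export
default_combo_k <- function() {
  c(emg = 7L, ofs = 8L, imu1 = 5L, imu2 = 4L, imus = 10L,
    imus_ofs = 13L, all = 33L)
}

#' Sensor-ablation protocol
#'
#' For each sensor combination: restrict the feature table to that
#' combination's columns, train a gradient-boosted model on the training
#' subjects, re-rank features by split importance, keep the top `k`, retrain
#' on those, and evaluate on the held-out test subjects.
#'
#' @param table normalized feature tibble.
#' @param plan a [split_dataset()] plan.
#' @param combos combination labels (subset of `names(sensor_combos())`).
#' @param k named vector of per-combo feature budgets.
#' @param params gradient-boosted hyperparameters (e.g. the LOOCV winner).
#' @param seed training seed.
#' @return named list of `model_report`s, one per combination.
#' @export
ablate_sensors <- function(table, plan, combos = names(sensor_combos()),
                           k = default_combo_k(),
                           params = default_grid("lgbm")[1L, , drop = FALSE],
                           seed = 1L) {
  all_combos <- sensor_combos()
  combos <- match.arg(combos, names(all_combos), several.ok = TRUE)
  train_tbl <- table[table$subject_id %in% plan$train_subjects, , drop = FALSE]
  test_tbl <- table[table$subject_id %in% plan$test_subjects, , drop = FALSE]
  reports <- lapply(combos, function(cb) {
    feats <- feature_names(all_combos[[cb]])
    k_cb <- if (cb %in% names(k)) as.integer(k[[cb]]) else length(feats)
    if (k_cb > length(feats)) {
      stop("k = ", k_cb, " exceeds the ", length(feats),
           " features available for combo '", cb, "'")
    }
    fit_full <- train_classifier(
      feature_matrix(train_tbl, feats), train_tbl$state, "lgbm",
      params, seed = seed
    )
    top <- select_top_features(rank_importance(fit_full), k_cb)
    fit <- train_classifier(
      feature_matrix(train_tbl, top), train_tbl$state, "lgbm",
      params, seed = seed
    )
    build_report(fit, test_tbl,
                 metadata = list(sensor_combo = cb, n_features = k_cb,
                                 seed = seed))
  })
  stats::setNames(reports, combos)
}
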