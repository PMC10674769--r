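test_that("subject-wise split obeys the ratio arithmetic and determinism", {
  ids30 <- sprintf("S%02d", 1:30)
  p <- split_dataset(ids30, 0.7, seed = 1)
  expect_length(p$train_subjects, 21)
  expect_length(p$test_subjects, 9)
  p10 <- split_dataset(sprintf("S%02d", 1:10), 0.7, seed = 1)
  expect_length(p10$train_subjects, 7)
  expect_length(p10$test_subjects, 3)
  expect_identical(split_dataset(ids30, 0.7, seed = 5),
                   split_dataset(ids30, 0.7, seed = 5))
  expect_error(split_dataset(ids30, 1.2), "ratio")
  expect_error(split_dataset("S01"), "at least 2")
})

test_that("train and test subjects never overlap and cover the cohort", {
  for (seed in 1:10) {
    p <- split_dataset(sprintf("S%02d", 1:17), 0.7, seed = seed)
    expect_length(intersect(p$train_subjects, p$test_subjects), 0)
    expect_setequal(c(p$train_subjects, p$test_subjects), sprintf("S%02d", 1:17))
  }
})

test_that("LOOCV uses one fold per training subject, shared across candidates", {
  tab <- toy_features(6, 15)
  plan <- split_dataset(unique(tab$subject_id), 0.7, seed = 2)
  cv <- loocv_grid_search(tab, plan, family = "dt", seed = 2)
  expect_setequal(cv$fold_subjects, plan$train_subjects)
  expect_length(cv$fold_subjects, length(plan$train_subjects))
  expect_equal(nrow(cv$cv_results), nrow(default_grid("dt")))
  expect_true(all(cv$cv_results$cv_accuracy >= 0 & cv$cv_results$cv_accuracy <= 1))
  # singleton grid returns that candidate
  g1 <- default_grid("dt")[1, , drop = FALSE]
  cv1 <- loocv_grid_search(tab, plan, family = "dt", grid = g1, seed = 2)
  expect_equal(cv1$best_params, g1)
  expect_error(loocv_grid_search(tab, plan, grid = default_grid("dt")[0, ]),
               "empty")
})

test_that("grid search is deterministic under a fixed seed", {
  tab <- toy_features(5, 12)
  plan <- split_dataset(unique(tab$subject_id), 0.7, seed = 3)
  a <- loocv_grid_search(tab, plan, family = "lgbm", seed = 3)
  b <- loocv_grid_search(tab, plan, family = "lgbm", seed = 3)
  expect_identical(a$best_params, b$best_params)
  expect_equal(a$cv_results$cv_accuracy, b$cv_results$cv_accuracy)
})

test_that("every model family trains and predicts the toy problem above chance", {
  tab <- toy_features(6, 18)
  plan <- split_dataset(unique(tab$subject_id), 0.7, seed = 4)
  tr <- tab[tab$subject_id %in% plan$train_subjects, ]
  te <- tab[tab$subject_id %in% plan$test_subjects, ]
  for (fam in c("lgbm", "rf", "bc", "et", "dt")) {
    fit <- train_classifier(feature_matrix(tr), tr$state, fam, seed = 4)
    pred <- predict_states(fit, feature_matrix(te))
    acc <- mean(pred == te$state)
    expect_gt(acc, 1 / 3)
  }
})

test_that("split-importance counts every split, and only splits", {
  tab <- toy_features(6, 18)
  fit <- train_classifier(feature_matrix(tab), tab$state, "lgbm", seed = 5)
  rk <- rank_importance(fit)
  # completeness: a permutation of the model's feature set
  expect_setequal(rk$feature, fit$features)
  expect_equal(nrow(rk), 63)
  expect_true(all(diff(rk$splits) <= 0))
  expect_true(all(rk$splits >= 0))
  # oracle: total split count from the text dump of the ensemble
  dump <- xgboost::xgb.dump(fit$model)
  n_splits <- sum(grepl("yes=", dump)) # internal nodes in the text dump
  expect_equal(sum(rk$splits), n_splits)
  # cross-check against the library's own frequency-based importance
  imp <- xgboost::xgb.importance(model = fit$model)
  top_lib <- imp$Feature[which.max(imp$Frequency)]
  expect_equal(rk$feature[1], top_lib)
  expect_error(rank_importance(train_classifier(feature_matrix(tab),
                                                tab$state, "dt", seed = 1)),
               "gradient-boosted")
})

test_that("a feature constant across training rows is never split on", {
  tab <- toy_features(5, 15)
  tab$IMU2_AccZ_Amp <- 3.14
  fit <- train_classifier(feature_matrix(tab), tab$state, "lgbm", seed = 6)
  rk <- rank_importance(fit)
  expect_equal(rk$splits[rk$feature == "IMU2_AccZ_Amp"], 0L)
})

test_that("top-k selection is a nested prefix of the ranking", {
  tab <- toy_features(5, 15)
  fit <- train_classifier(feature_matrix(tab), tab$state, "lgbm", seed = 7)
  rk <- rank_importance(fit)
  expect_length(select_top_features(rk, 1), 1)
  expect_equal(select_top_features(rk, nrow(rk)), rk$feature)
  expect_true(all(select_top_features(rk, 5) %in% select_top_features(rk, 7)))
  expect_true(all(select_top_features(rk, 7) %in% select_top_features(rk, 11)))
  expect_error(select_top_features(rk, 0), "k must")
  expect_error(select_top_features(rk, 64), "k must")
})

test_that("sensor combinations expose the expected feature budgets", {
  cb <- sensor_combos()
  expect_length(feature_names(cb$emg), 7)
  expect_length(feature_names(cb$ofs), 8)
  expect_length(feature_names(cb$imu1), 24)
  expect_length(feature_names(cb$imus), 48)
  expect_length(feature_names(cb$imus_ofs), 56)
  expect_length(feature_names(cb$all), 63)
})

test_that("sensor ablation restricts features per combo and reports results", {
  tab <- toy_features(6, 15)
  plan <- split_dataset(unique(tab$subject_id), 0.7, seed = 8)
  reps <- ablate_sensors(tab, plan, combos = c("emg", "imus", "all"),
                         k = c(emg = 7, imus = 10, all = 63), seed = 8)
  expect_named(reps, c("emg", "imus", "all"))
  expect_true(all(reps$emg$features %in% feature_names("emg")))
  expect_length(reps$emg$features, 7)
  expect_length(reps$all$features, 63)
  expect_true(all(reps$imus$features %in% feature_names(c("imu1", "imu2"))))
  # k exceeding a combo's catalog is refused
  expect_error(ablate_sensors(tab, plan, combos = "emg", k = c(emg = 8)),
               "exceeds")
})
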