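#!/usr/bin/env Rscript
# Step 3 — subject-wise split, LOOCV grid search, importance ranking.
#
# Splits the 30 subjects 70:30 (21 train / 9 test), tunes the
# gradient-boosted classifier by leave-one-subject-out cross-validation
# (k = 21 folds), fits the winner on all training subjects, ranks the
# features by split importance, and evaluates on the held-out subjects.

library(armfatigue)

seed <- 1L
feats <- tibble::as_tibble(data.table::fread("results/features.csv"))
feats$state <- factor(feats$state, levels = fatigue_states())

plan <- split_dataset(unique(feats$subject_id), ratio = 0.7, seed = seed)
cat("Train subjects:", length(plan$train_subjects),
    "| test subjects:", length(plan$test_subjects), "\n")
jsonlite::write_json(unclass(plan), "results/split.json", auto_unbox = TRUE)

cv <- loocv_grid_search(feats, plan, family = "lgbm", seed = seed)
data.table::fwrite(cv$cv_results, "results/cv_results.csv")
cat("LOOCV folds:", length(cv$fold_subjects), "\n")
cat(sprintf("Best CV accuracy: %.1f%%\n", 100 * max(cv$cv_results$cv_accuracy)))

train_tbl <- feats[feats$subject_id %in% plan$train_subjects, ]
fit <- train_classifier(feature_matrix(train_tbl), train_tbl$state, "lgbm",
                        cv$best_params, seed = seed)
imp <- rank_importance(fit)
data.table::fwrite(imp, "results/importance.csv")
cat("Top 5 features by split importance:\n")
print(utils::head(imp, 5))

report <- build_report(fit, feats[feats$subject_id %in% plan$test_subjects, ],
                       metadata = list(sensor_combo = "all", seed = seed))
write_report(report, "results/report_all_63.json")
print(report)
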