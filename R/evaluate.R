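#' Confusion matrix over the three fatigue states
#'
#' Rows are the true state, columns the predicted state, ordered LF, MOF,
#' HF.
#'
#' @param truth,predicted equal-length label vectors over the fatigue
#'   states.
#' @return 3 x 3 integer matrix.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and prediction lengths differ")
  }
  lv <- fatigue_states()
  bad <- setdiff(unique(c(as.character(truth), as.character(predicted))), lv)
  if (length(bad) > 0) stop("unknown label(s): ", paste(bad, collapse = ", "))
  truth <- factor(as.character(truth), levels = lv)
  predicted <- factor(as.character(predicted), levels = lv)
  m <- table(truth = truth, predicted = predicted)
  matrix(as.integer(m), 3L, 3L, dimnames = dimnames(m))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is the diagonal fraction `TP / N`. Precision and recall are
#' aggregated per-class ratios under the chosen averaging: `micro` pools the
#' per-class counts (for single-label multiclass problems micro precision =
#' micro recall = accuracy, an algebraic identity), `weighted` averages the
#' per-class ratios weighted by true-class support. F1 is the harmonic mean
#' `2 * P * R / (P + R)` of the aggregated precision and recall.
#'
#' @param cm confusion matrix from [confusion()].
#' @param averaging `"weighted"` or `"micro"`.
#' @return named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
metrics <- function(cm, averaging = c("weighted", "micro")) {
  averaging <- match.arg(averaging)
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  accuracy <- sum(tp) / n
  if (averaging == "micro") {
    precision <- recall <- accuracy
  } else {
    row_s <- rowSums(cm)
    col_s <- colSums(cm)
    absent <- row_s == 0 & col_s == 0
    if (any(absent)) {
      warning("state(s) absent from truth and prediction contribute 0: ",
              paste(rownames(cm)[absent], collapse = ", "))
    }
    prec_c <- ifelse(col_s > 0, tp / col_s, 0)
    rec_c <- ifelse(row_s > 0, tp / row_s, 0)
    w <- row_s / n
    precision <- sum(w * prec_c)
    recall <- sum(w * rec_c)
  }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(accuracy = accuracy, precision = precision, recall = recall, f1 = f1)
}

#' Evaluate a trained model on held-out cycles and build a report
#'
#' Predicts the fatigue state of every test cycle, forms the confusion
#' matrix and both metric averagings, and bundles them with the model's
#' configuration into a machine-readable report.
#'
#' @param fit a `fatigue_model`.
#' @param test_tbl feature tibble of held-out cycles (with `state`).
#' @param metadata optional named list merged into the report (e.g. sensor
#'   combo, seed).
#' @return a `model_report` list: `family`, `hyperparameters`, `features`,
#'   `n_test`, `confusion`, `metrics_weighted`, `metrics_micro`, plus
#'   metadata fields.
#' @export
build_report <- function(fit, test_tbl, metadata = list()) {
  stopifnot(inherits(fit, "fatigue_model"))
  if (nrow(test_tbl) == 0L) stop("empty test set")
  pred <- predict_states(fit, feature_matrix(test_tbl, fit$features))
  cm <- confusion(test_tbl$state, pred)
  structure(c(
    list(
      family = fit$family,
      hyperparameters = fit$params,
      features = fit$features,
      n_test = nrow(test_tbl),
      confusion = cm,
      metrics_weighted = metrics(cm, "weighted"),
      metrics_micro = metrics(cm, "micro")
    ),
    metadata
  ), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report>", x$family,
      if (!is.null(x$sensor_combo)) paste0("[", x$sensor_combo, "]"),
      "-", length(x$features), "features,", x$n_test, "test cycles\n")
  cat(sprintf(
    "  accuracy %.1f%%  precision %.1f%%  recall %.1f%%  F1 %.1f%% (weighted)\n",
    100 * x$metrics_weighted[["accuracy"]],
    100 * x$metrics_weighted[["precision"]],
    100 * x$metrics_weighted[["recall"]],
    100 * x$metrics_weighted[["f1"]]
  ))
  invisible(x)
}

#' Write a model report as JSON
#'
#' @param report a `model_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$confusion <- list(
    labels = rownames(report$confusion),
    counts = unname(apply(report$confusion, 1L, as.list))
  )
  out$metrics_weighted <- as.list(report$metrics_weighted)
  out$metrics_micro <- as.list(report$metrics_micro)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
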