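# Pain-state classification from patient AU time courses with a
# gradient-boosted tree ensemble (XGBoost) and SHAP-based ranking of AU
# importance. Frames are the unit of classification; validation is grouped
# (leave-subjects-out) k-fold so no subject contributes to both the
# training and test side of a fold.

#' Assemble a labelled frame table from a pain session
#'
#' One row per frame inside a moderate-pain or innocuous-pressure
#' stimulation block; rest, anticipation and rating frames are excluded.
#' Pain frames get label 1.
#'
#' @param recording the patient's `au_recording`.
#' @param events the session `event_table` with `pain_moderate` /
#'   `pain_innocuous` blocks.
#' @return a `data.frame` of class `frame_table` with `subject_id`,
#'   `block_index`, `condition` (`"pain"` / `"innocuous"`), `label` and the
#'   20 AU feature columns.
#' @export
assemble_frames <- function(recording, events) {
  stopifnot(inherits(recording, "au_recording"))
  stim <- events[events$condition %in% c("pain_moderate", "pain_innocuous"), ,
                 drop = FALSE]
  stim <- stim[order(stim$run_index, stim$onset), , drop = FALSE]
  if (nrow(stim) == 0L) {
    stop("empty-input error: no labelled pain/innocuous blocks in events")
  }
  rows <- vector("list", nrow(stim))
  for (b in seq_len(nrow(stim))) {
    seg <- slice_frames(recording, stim$onset[b], stim$duration[b])
    cond <- ifelse(stim$condition[b] == "pain_moderate", "pain", "innocuous")
    rows[[b]] <- data.frame(subject_id = recording$subject_id,
                            block_index = b, condition = cond,
                            label = as.integer(cond == "pain"), seg,
                            check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("frame_table", "data.frame")
  out
}

frame_features <- function(frames) {
  setdiff(names(frames), c("subject_id", "block_index", "condition", "label"))
}

#' Gradient-boosted pain-state classifier with grouped cross-validation
#'
#' Trains an XGBoost binary classifier (pain vs innocuous) on framewise AU
#' features under grouped k-fold cross-validation: subjects are assigned
#' to folds, so no subject appears in both train and test of any fold.
#' AUC (threshold-free), precision and recall (at `threshold`) are pooled
#' over the held-out predictions; a final model is fitted on all rows for
#' SHAP ranking and prediction on new data.
#'
#' @param frames a `frame_table` from [assemble_frames()] (rows from
#'   several subjects, both classes present).
#' @param k number of grouped folds (capped at the number of subjects).
#' @param nrounds,max_depth,eta boosting hyperparameters (shallow trees by
#'   default).
#' @param threshold posterior threshold for precision/recall.
#' @param seed integer seed (fold assignment and boosting).
#' @return an object of class `pain_classifier` with `auc`, `precision`,
#'   `recall`, per-fold metrics, pooled held-out `predictions`, the fitted
#'   `model` and the `cv_scheme` descriptor.
#' @export
pain_classifier <- function(frames, k = 5L, nrounds = 200L, max_depth = 3L,
                            eta = 0.1, threshold = 0.5, seed = 1L) {
  feats <- frame_features(frames)
  y <- frames$label
  if (length(unique(y)) < 2L) {
    stop("degenerate-label error: both classes must be present")
  }
  subjects <- unique(frames$subject_id)
  if (length(subjects) < 2L) {
    stop("CV error: grouped cross-validation needs >= 2 subjects")
  }
  k <- min(as.integer(k), length(subjects))
  set.seed(derive_seed(seed, "folds"))
  fold_of <- sample(rep_len(seq_len(k), length(subjects)))
  names(fold_of) <- sample(subjects)
  X <- as.matrix(frames[feats])
  xgb_params <- list(objective = "binary:logistic", max_depth = max_depth,
                     eta = eta, nthread = 1L, eval_metric = "logloss")
  preds <- rep(NA_real_, nrow(frames))
  fold_stats <- vector("list", k)
  for (f in seq_len(k)) {
    test <- frames$subject_id %in% names(fold_of)[fold_of == f]
    set.seed(derive_seed(seed, "boost", f))
    booster <- xgboost::xgb.train(
      params = xgb_params,
      data = xgboost::xgb.DMatrix(X[!test, , drop = FALSE], label = y[!test]),
      nrounds = nrounds, verbose = 0)
    preds[test] <- predict(booster, xgboost::xgb.DMatrix(X[test, , drop = FALSE]))
    fold_stats[[f]] <- data.frame(
      fold = f, n_test = sum(test),
      n_subjects_test = sum(fold_of == f),
      auc = if (length(unique(y[test])) == 2L) {
        as.numeric(pROC::auc(pROC::roc(y[test], preds[test], quiet = TRUE,
                                       direction = "<", levels = c(0, 1))))
      } else NA_real_)
  }
  auc <- as.numeric(pROC::auc(pROC::roc(y, preds, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  hard <- as.integer(preds >= threshold)
  tp <- sum(hard == 1L & y == 1L)
  precision <- if (sum(hard == 1L)) tp / sum(hard == 1L) else NA_real_
  recall <- tp / sum(y == 1L)
  set.seed(derive_seed(seed, "final"))
  final <- xgboost::xgb.train(
    params = xgb_params, data = xgboost::xgb.DMatrix(X, label = y),
    nrounds = nrounds, verbose = 0)
  structure(list(auc = auc, precision = precision, recall = recall,
                 threshold = threshold,
                 per_fold = do.call(rbind, fold_stats),
                 predictions = data.frame(subject_id = frames$subject_id,
                                          label = y, posterior = preds),
                 fold_of = fold_of,
                 cv_scheme = sprintf("grouped %d-fold (leave-subjects-out)", k),
                 model = final, features = feats,
                 hyperparams = list(nrounds = nrounds, max_depth = max_depth,
                                    eta = eta),
                 seed = seed),
            class = "pain_classifier")
}

#' @export
print.pain_classifier <- function(x, ...) {
  cat(sprintf("<pain_classifier> XGBoost, %s\n", x$cv_scheme))
  cat(sprintf("  pooled held-out AUC %.3f, precision %.3f, recall %.3f (threshold %.2f)\n",
              x$auc, x$precision, x$recall, x$threshold))
  invisible(x)
}

#' @export
summary.pain_classifier <- function(object, ...) {
  print(object)
  cat("  per-fold held-out AUC:\n")
  print(object$per_fold, row.names = FALSE)
  invisible(object)
}

#' @export
predict.pain_classifier <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else as.matrix(newdata[object$features])
  if (!identical(colnames(X), object$features)) {
    stop("schema error: feature columns do not match the fitted model")
  }
  predict(object$model, xgboost::xgb.DMatrix(X))
}

#' Rank AU importance by mean absolute SHAP value
#'
#' Computes TreeSHAP per-frame contributions of the fitted booster on the
#' frame table it scores and ranks all 20 AUs by descending mean |SHAP|;
#' ties are broken deterministically by AU label.
#'
#' @param fit a [pain_classifier()] object.
#' @param frames a `frame_table` to attribute over (must carry the model's
#'   feature columns).
#' @return a `data.frame` of class `shap_ranking` with `rank`, `au_label`
#'   and `mean_abs_shap`.
#' @export
rank_shap <- function(fit, frames) {
  stopifnot(inherits(fit, "pain_classifier"))
  feats <- frame_features(frames)
  if (!setequal(feats, fit$features)) {
    stop("schema error: frame table features do not match the fitted model")
  }
  X <- as.matrix(frames[fit$features])
  contrib <- predict(fit$model, xgboost::xgb.DMatrix(X), predcontrib = TRUE)
  contrib <- contrib[, fit$features, drop = FALSE]
  m <- colMeans(abs(contrib))
  ord <- order(-m, names(m))
  out <- data.frame(rank = seq_along(m), au_label = names(m)[ord],
                    mean_abs_shap = unname(m[ord]))
  class(out) <- c("shap_ranking", "data.frame")
  out
}

#' @export
print.shap_ranking <- function(x, n = 10L, ...) {
  cat("<shap_ranking> mean |SHAP| per AU (descending)\n")
  print.data.frame(utils::head(x, n), row.names = FALSE)
  if (nrow(x) > n) cat(sprintf("  ... %d more\n", nrow(x) - n))
  invisible(x)
}

#' @export
plot.shap_ranking <- function(x, ...) {
  op <- graphics::par(mar = c(4, 9, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(x$mean_abs_shap), names.arg = rev(x$au_label),
                    horiz = TRUE, las = 1, cex.names = 0.7,
                    xlab = "mean |SHAP|", ...)
  invisible(x)
}
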