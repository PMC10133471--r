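#' One-vs-rest confusion counts
#'
#' For each class, counts true/false positives and negatives treating that
#' class against the rest.
#'
#' @param true,pred Integer vectors of 0-based class indices.
#' @param n_classes Number of classes.
#' @return Data frame of class `"confusion_counts"` with columns `class`,
#'   `TP`, `TN`, `FP`, `FN`; each row sums to `length(true)`.
#' @export
confusion_counts <- function(true, pred, n_classes) {
  stopifnot(length(true) == length(pred))
  n <- length(true)
  out <- data.frame(class = seq_len(n_classes) - 1L, TP = 0L, TN = 0L,
                    FP = 0L, FN = 0L)
  for (k in seq_len(n_classes) - 1L) {
    tp <- sum(true == k & pred == k)
    fp <- sum(true != k & pred == k)
    fn <- sum(true == k & pred != k)
    out[out$class == k, c("TP", "TN", "FP", "FN")] <-
      c(tp, n - tp - fp - fn, fp, fn)
  }
  class(out) <- c("confusion_counts", "data.frame")
  out
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Per class (one-vs-rest): `ACC = (TP + TN) / (TP + FP + FN + TN)`,
#' `SEN = TP / (TP + FN)`, `SPE = TN / (TN + FP)`. Multi-class values are
#' macro-averages of the per-class values. A zero denominator yields a
#' flagged 0 rather than NaN.
#'
#' @param counts A [confusion_counts()] data frame (or any data frame with
#'   columns `TP`, `TN`, `FP`, `FN`).
#' @return List with `acc`, `sen`, `spe` (proportions in `[0, 1]`),
#'   `per_class` (data frame) and `flagged` (logical: some denominator was
#'   zero).
#' @export
metrics_from_confusion <- function(counts) {
  stopifnot(all(c("TP", "TN", "FP", "FN") %in% names(counts)),
            all(counts$TP >= 0), all(counts$TN >= 0),
            all(counts$FP >= 0), all(counts$FN >= 0))
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  acc <- (counts$TP + counts$TN) /
    (counts$TP + counts$FP + counts$FN + counts$TN)
  sen <- safe_div(counts$TP, counts$TP + counts$FN)
  spe <- safe_div(counts$TN, counts$TN + counts$FP)
  flagged <- any(counts$TP + counts$FN == 0) || any(counts$TN + counts$FP == 0)
  per_class <- data.frame(class = counts$class %||% seq_along(acc) - 1L,
                          acc = acc, sen = sen, spe = spe)
  list(acc = mean(acc), sen = mean(sen), spe = mean(spe),
       per_class = per_class, flagged = flagged)
}

#' Grouped, stratified k-fold assignment
#'
#' Assigns whole trials to folds so that segments of one trial never
#' straddle the train/test boundary (no leakage), while balancing classes
#' across folds: within each class, trials are dealt round-robin to folds.
#'
#' @param trial_ids Character vector, one id per segment.
#' @param y 0-based class index per segment.
#' @param k Number of folds.
#' @return Integer vector of fold assignments (1..k) per segment.
#' @export
grouped_stratified_folds <- function(trial_ids, y, k) {
  stopifnot(k >= 2, length(trial_ids) == length(y))
  first <- !duplicated(trial_ids)
  trials <- data.frame(id = trial_ids[first], y = y[first])
  fold_of <- integer(nrow(trials))
  for (cls in unique(trials$y)) {
    idx <- which(trials$y == cls)
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  names(fold_of) <- trials$id
  per_class_folds <- tapply(fold_of, trials$y,
                            function(f) length(unique(f)))
  if (any(per_class_folds < k))
    stop("stratification error: some class has fewer trials than folds, ",
         "so it would be absent from a training split", call. = FALSE)
  unname(fold_of[trial_ids])
}

#' k-fold cross-validated evaluation
#'
#' Splits the segments into `k` grouped, class-stratified folds; for each
#' fold trains a classifier on the remaining folds and evaluates
#' macro-averaged accuracy, sensitivity and specificity on the held-out
#' fold; reports mean and standard deviation across folds (as
#' percentages).
#'
#' @param segments A `segment_batch`.
#' @param classifier A list with functions `fit(train_batch)` returning a
#'   fitted state and `predict(state, batch)` returning 0-based labels —
#'   see [gdnet_classifier()].
#' @param k Number of folds (default 10).
#' @param n_classes Number of classes (defaults to `max(y) + 1`).
#' @return List of class `"metrics_report"` with `per_fold` (data frame:
#'   fold, acc, sen, spe in percent), `mean` and `sd` (named vectors), `k`.
#' @export
kfold_evaluate <- function(segments, classifier, k = 10L,
                           n_classes = max(segments$y) + 1L) {
  stopifnot(inherits(segments, "segment_batch"), k >= 2,
            length(segments$y) >= k)
  folds <- grouped_stratified_folds(segments$source_trial_ids, segments$y, k)
  per_fold <- data.frame()
  for (fold in seq_len(k)) {
    train <- subset_segments(segments, which(folds != fold))
    test <- subset_segments(segments, which(folds == fold))
    state <- classifier$fit(train)
    pred <- classifier$predict(state, test)
    m <- metrics_from_confusion(confusion_counts(test$y, pred, n_classes))
    per_fold <- rbind(per_fold, data.frame(
      fold = fold, acc = 100 * m$acc, sen = 100 * m$sen, spe = 100 * m$spe))
  }
  structure(list(
    per_fold = per_fold,
    mean = vapply(per_fold[c("acc", "sen", "spe")], mean, numeric(1)),
    sd = vapply(per_fold[c("acc", "sen", "spe")], stats::sd, numeric(1)),
    k = k), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (macro one-vs-rest, %%):\n", x$k))
  for (m in c("acc", "sen", "spe"))
    cat(sprintf("  %s: %.2f +/- %.2f\n", toupper(m), x$mean[[m]], x$sd[[m]]))
  invisible(x)
}

#' Network classifier for k-fold evaluation
#'
#' Wraps model building, initialisation and training into the
#' fit/predict interface used by [kfold_evaluate()]. A fraction of each
#' training split (grouped by trial) is held out as the early-stopping
#' validation set.
#'
#' @param gcfg A [gdnet_config()].
#' @param tcfg A [train_config()].
#' @param val_fraction Fraction of training trials used for validation.
#' @return A classifier list with `fit` and `predict`.
#' @export
gdnet_classifier <- function(gcfg, tcfg = train_config(),
                             val_fraction = 0.15) {
  list(
    fit = function(train_batch) {
      ids <- unique(train_batch$source_trial_ids)
      old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
      set.seed(tcfg$seed)
      n_val <- max(1L, round(val_fraction * length(ids)))
      val_ids <- sample(ids, n_val)
      val_idx <- which(train_batch$source_trial_ids %in% val_ids)
      tr_idx <- setdiff(seq_along(train_batch$y), val_idx)
      model <- build_model(gcfg, dim(train_batch$X)[2])
      model <- init_weights(model, seed = tcfg$seed, sd = tcfg$init_sd)
      train_model(model, subset_segments(train_batch, tr_idx),
                  subset_segments(train_batch, val_idx), tcfg)$model
    },
    predict = function(state, batch) predict_classes(state, batch)
  )
}
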