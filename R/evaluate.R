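#' Confusion-matrix summary of binary predictions
#'
#' Error = (FP + FN) / n. Sensitivity is the true-positive rate with the
#' second label level (G2, the effect-injected group) as the positive class;
#' specificity is the true-negative rate on the first level (G1). A class
#' absent from the truth leaves the corresponding rate NA.
#'
#' @param predicted,truth factors (or vectors coercible to the same two
#'   levels) of equal length.
#' @return named list with `error`, `sensitivity`, `specificity`.
#' @export
confusionSummary <- function(predicted, truth) {
  truth <- as.factor(truth)
  if (nlevels(truth) > 2L) stop("binary labels required")
  predicted <- factor(predicted, levels = levels(truth))
  if (length(predicted) != length(truth)) stop("length mismatch")
  lev <- levels(truth)
  pos <- lev[2]; neg <- lev[1]
  isPos <- truth == pos
  error <- mean(predicted != truth)
  sensitivity <- if (any(isPos)) mean(predicted[isPos] == pos) else NA_real_
  specificity <- if (any(!isPos)) mean(predicted[!isPos] == neg) else NA_real_
  list(error = error, sensitivity = sensitivity, specificity = specificity)
}

.missingEstimate <- function(method, n, reason) {
  new("PerformanceEstimate", method = method, error = NA_real_,
      sensitivity = NA_real_, specificity = NA_real_,
      predictions = character(), nEval = as.integer(n), missing = TRUE,
      reason = reason)
}

.estimateFromPredictions <- function(method, predictions, truth) {
  cs <- confusionSummary(predictions, truth)
  new("PerformanceEstimate", method = method, error = cs$error,
      sensitivity = cs$sensitivity, specificity = cs$specificity,
      predictions = as.character(predictions), nEval = length(truth),
      missing = FALSE, reason = "")
}

#' Leave-one-out cross-validation performance
#'
#' For each sample i the classifier is trained on the remaining n - 1 samples
#' with the (already tuned) parameters held fixed, and sample i is predicted.
#' The aggregate error, sensitivity (positive class G2) and specificity are
#' computed from the n hold-out predictions. LDA degeneracy (p >= n - 1) and
#' training folds that lose a class entirely are recorded as a missing
#' estimate, never as a crash.
#'
#' @param method classifier key.
#' @param params a [TunedParams] or named list (ignored for `lda`).
#' @param dataset a [SimulatedSet], [FeatureTable] or `list(X =, y =)`.
#' @return a [PerformanceEstimate].
#' @export
loocv <- function(method, params, dataset) {
  xy <- .asXY(dataset)
  n <- nrow(xy$X)
  if (n < 2L) stop("n must be >= 2")
  if (nlevels(droplevels(xy$y)) < 2L) stop("both classes must be present")
  pred <- factor(rep(NA_character_, n), levels = levels(xy$y))
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (nlevels(droplevels(xy$y[tr])) < 2L)
      return(.missingEstimate(method, n, "a training fold lost a class"))
    p_i <- tryCatch(
      fitPredict(method, params,
                 list(X = xy$X[tr, , drop = FALSE], y = xy$y[tr]),
                 xy$X[i, , drop = FALSE]),
      classiSim_lda_degeneracy = function(e) e)
    if (inherits(p_i, "condition"))
      return(.missingEstimate(method, n, conditionMessage(p_i)))
    pred[i] <- p_i
  }
  .estimateFromPredictions(method, pred, xy$y)
}

#' k-fold cross-validation performance
#'
#' Stratified fold construction (class ratios per fold within one of
#' balanced); with `folds = n` this reduces exactly to [loocv()]. Fold
#' assignment consumes the current RNG stream.
#'
#' @inheritParams loocv
#' @param folds number of folds (<= n).
#' @return a [PerformanceEstimate].
#' @export
kfoldCV <- function(method, params, dataset, folds = 10L) {
  xy <- .asXY(dataset)
  n <- nrow(xy$X)
  if (folds > n) stop("folds must be <= n")
  fold <- .stratifiedFolds(xy$y, folds)
  pred <- factor(rep(NA_character_, n), levels = levels(xy$y))
  for (f in seq_len(folds)) {
    te <- which(fold == f)
    if (!length(te)) next
    tr <- which(fold != f)
    if (nlevels(droplevels(xy$y[tr])) < 2L)
      return(.missingEstimate(method, n, "a training fold lost a class"))
    p_f <- tryCatch(
      fitPredict(method, params,
                 list(X = xy$X[tr, , drop = FALSE], y = xy$y[tr]),
                 xy$X[te, , drop = FALSE]),
      classiSim_lda_degeneracy = function(e) e)
    if (inherits(p_f, "condition"))
      return(.missingEstimate(method, n, conditionMessage(p_f)))
    pred[te] <- p_f
  }
  .estimateFromPredictions(method, pred, xy$y)
}

#' Flatten a performance estimate to one record
#'
#' @param est a [PerformanceEstimate].
#' @return one-row data.frame (method, error, sensitivity, specificity,
#'   n, missing).
#' @export
asRecord <- function(est) {
  data.frame(method = est@method, error = est@error,
             sensitivity = est@sensitivity, specificity = est@specificity,
             n = est@nEval, missing = est@missing, stringsAsFactors = FALSE)
}
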