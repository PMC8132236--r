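#' Area under the ROC curve (Mann-Whitney form)
#'
#' P(score_pos > score_neg) + 0.5 P(tie), computed from midranks.
#'
#' @param scores numeric prediction scores.
#' @param y binary outcomes (0/1).
#' @export
roc_auc <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(scores)                    # midranks handle ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix rates at a probability cutoff
#'
#' Predictions are positive when score >= cutoff.
#'
#' @param scores predicted probabilities.
#' @param y binary outcomes.
#' @param cutoff decision threshold (default 0.5).
#' @return named vector: FPR, FNR, TPR, TNR, balanced_accuracy
#'   (= (TPR + TNR) / 2).
#' @export
confusion_rates <- function(scores, y, cutoff = 0.5) {
  y <- as.integer(y)
  yhat <- as.integer(scores >= cutoff)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  tpr <- sum(yhat == 1 & y == 1) / n1
  tnr <- sum(yhat == 0 & y == 0) / n0
  c(FPR = 1 - tnr, FNR = 1 - tpr, TPR = tpr, TNR = tnr,
    balanced_accuracy = (tpr + tnr) / 2)
}

#' Between-group disparity of a metric
#'
#' Absolute difference for two groups; range (max - min) for more.
#'
#' @param values one metric value per group.
#' @export
group_disparity <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least two groups")
  max(values) - min(values)
}

#' Per-group mean squared error of coefficient estimates
#'
#' (1/p) || beta_hat_k - beta_k ||_2^2 per group; intercepts excluded.
#'
#' @param est,truth `coef_set` objects on the same feature space.
#' @export
coef_mse <- function(est, truth) {
  stopifnot(est$p == truth$p, est$K == truth$K)
  stats::setNames(colMeans((est$beta - truth$beta)^2), est$labels)
}

#' Per-group variable-selection rates
#'
#' TPR: fraction of truly non-zero coordinates detected as non-zero
#' (|estimate| > zero_tol); TNR: fraction of true zeros left at zero.
#'
#' @inheritParams coef_mse
#' @param zero_tol magnitude below which an estimate counts as zero.
#' @return K x 2 matrix with columns TPR, TNR (NA when a group has no
#'   true non-zeros / zeros).
#' @export
selection_rates <- function(est, truth, zero_tol = 1e-8) {
  stopifnot(est$p == truth$p, est$K == truth$K)
  out <- matrix(NA_real_, est$K, 2, dimnames = list(est$labels, c("TPR", "TNR")))
  for (k in seq_len(est$K)) {
    nz <- abs(truth$beta[, k]) > 0
    sel <- abs(est$beta[, k]) > zero_tol
    if (any(nz)) out[k, "TPR"] <- mean(sel[nz])
    if (any(!nz)) out[k, "TNR"] <- mean(!sel[!nz])
  }
  out
}

#' Brier score
#'
#' Mean squared difference between predicted probability and outcome
#' (mean rather than sum, so folds or groups of unequal size are
#' comparable; the two differ by a constant factor within a fixed set).
#'
#' @inheritParams confusion_rates
#' @export
brier_score <- function(scores, y) {
  mean((scores - as.integer(y))^2)
}

#' Harmonic mean
#'
#' K / sum(1/v); never exceeds the arithmetic mean, with equality iff all
#' values are equal. Used to average groupwise AUCs robustly when group
#' sizes are unbalanced (the harmonic mean is dragged down by a single
#' badly-served group).
#'
#' @param values positive numbers.
#' @export
harmonic_mean <- function(values) {
  values <- as.numeric(values)
  if (any(values <= 0)) stop("harmonic mean requires positive values")
  length(values) / sum(1 / values)
}

#' Per-group evaluation of a fitted model
#'
#' @param fit a `fair_fit`.
#' @param data a `grouped_data` test set.
#' @param cutoff probability cutoff for the confusion rates.
#' @param truth optional true `coef_set` to add estimation / selection
#'   metrics.
#' @return data.frame, one row per group: AUC, Brier, FPR, FNR,
#'   balanced_accuracy, and (if truth given) coef_mse, sel_TPR, sel_TNR;
#'   plus an `auc_disparity` attribute.
#' @export
evaluate_fit <- function(fit, data, cutoff = 0.5, truth = NULL) {
  data <- validate_dataset(data)
  rows <- vector("list", data$K)
  for (k in seq_len(data$K)) {
    g <- data$groups[[k]]
    pr <- predict(fit, g$X, g$label)
    cr <- confusion_rates(pr, g$y, cutoff)
    rows[[k]] <- data.frame(
      group = g$label, n = length(g$y),
      auc = roc_auc(pr, g$y), brier = brier_score(pr, g$y),
      FPR = cr[["FPR"]], FNR = cr[["FNR"]],
      balanced_accuracy = cr[["balanced_accuracy"]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(truth)) {
    out$coef_mse <- as.numeric(coef_mse(fit$coefficients, truth))
    sr <- selection_rates(fit$coefficients, truth)
    out$sel_TPR <- sr[, "TPR"]
    out$sel_TNR <- sr[, "TNR"]
  }
  attr(out, "auc_disparity") <- group_disparity(out$auc)
  rownames(out) <- NULL
  out
}
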