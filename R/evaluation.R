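# Threshold-independent validation metrics, implemented natively.

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, with ties counted as one
#' half. Invariant under any strictly monotone transform of the scores.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
aucROC <- function(scores, labels) {
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve
#'
#' Average precision with step-wise interpolation: thresholds sweep the
#' unique score values from high to low, and each recall increment is
#' weighted by the precision at that threshold. Tied scores enter the
#' curve as one group, making the value well defined under ties. Preferred
#' over ROC AUC when presences are rare relative to background.
#'
#' @inheritParams aucROC
#' @return average precision in `(0, 1]`.
#' @export
aucPR <- function(scores, labels) {
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L)
  if (nPos == 0L) stop("need at least one positive", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; prevRecall <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1L)
    precision <- tp / sum(sel)
    recall <- tp / nPos
    ap <- ap + (recall - prevRecall) * precision
    prevRecall <- recall
  }
  ap
}

#' Sensitivity and specificity of a binary prediction
#'
#' @param predicted 0/1 predicted classes.
#' @param labels 0/1 true labels; both classes required.
#' @return named numeric: `sensitivity` (TP/(TP+FN)) and `specificity`
#'   (TN/(TN+FP)).
#' @export
sensSpec <- function(predicted, labels) {
  labels <- as.integer(labels); predicted <- as.integer(predicted)
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both classes must be present in labels", call. = FALSE)
  tp <- sum(predicted == 1L & labels == 1L)
  fn <- sum(predicted == 0L & labels == 1L)
  tn <- sum(predicted == 0L & labels == 0L)
  fp <- sum(predicted == 1L & labels == 0L)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Summarize metrics across ensemble iterations
#'
#' @param metrics data.frame with one row per iteration (as in
#'   [iterationMetrics()]).
#' @param columns metric columns to summarize.
#' @return data.frame with rows `mean` and `sd` (population SD).
#' @export
summarizeIterations <- function(metrics,
                                columns = c("auc_roc", "auc_pr",
                                            "sensitivity", "specificity")) {
  if (nrow(metrics) < 1L) stop("no iterations to summarize", call. = FALSE)
  m <- as.matrix(metrics[, columns, drop = FALSE])
  mu <- colMeans(m)
  sdv <- sqrt(colMeans(sweep(m, 2L, mu)^2))
  out <- rbind(mean = mu, sd = sdv)
  as.data.frame(out)
}
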