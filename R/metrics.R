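# Evaluation metrics: AUROC (Mann-Whitney), AUPRC (step-wise PR integration),
# F1 and accuracy at a fixed threshold, and fold aggregation.

#' Area under the ROC curve
#'
#' Mann-Whitney definition: the probability that a random positive is scored
#' above a random negative, with ties counting one half. Computed from rank
#' sums (midranks for ties), which equals the O(n^2) pair count exactly.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1).
#' @return AUROC in `[0, 1]`, or `NaN` (with a warning) when only one class
#'   is present.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    warning("AUROC undefined with a single class")
    return(NaN)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration of the precision-recall curve: examples are swept in
#' descending score order (tied scores processed as one block) and the area
#' accumulates `precision * delta_recall` at each step.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`, or `NaN` (with a warning) for single-class input.
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  if (n_pos == 0L || n_pos == length(labels)) {
    warning("AUPRC undefined with a single class")
    return(NaN)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- 0; fp <- 0; area <- 0; prev_recall <- 0
  i <- 1L
  n <- length(y)
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1L] == s[i]) j <- j + 1L
    tp <- tp + sum(y[i:j] == 1)
    fp <- fp + sum(y[i:j] == 0)
    recall <- tp / n_pos
    precision <- tp / (tp + fp)
    area <- area + precision * (recall - prev_recall)
    prev_recall <- recall
    i <- j + 1L
  }
  area
}

#' Compute the standard metric suite for one evaluation
#'
#' AUROC and AUPRC are threshold-free; F1 and accuracy use the fixed decision
#' threshold (scores at or above the threshold predict an interaction).
#'
#' @param scores Predicted probabilities.
#' @param labels Binary labels.
#' @param threshold Decision threshold for F1/accuracy (default 0.5).
#' @return A named list (`auroc`, `auprc`, `f1`, `accuracy`, `n`).
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(auroc = auroc(scores, labels),
       auprc = auprc(scores, labels),
       f1 = f1,
       accuracy = mean(pred == labels),
       n = length(labels))
}

#' Aggregate per-fold metrics into mean and standard deviation
#'
#' @param fold_metrics List of metric lists from [compute_metrics()].
#' @return A `metrics_report`: list with `per_fold` (data frame) and `summary`
#'   (data frame of mean and SD per metric).
#' @export
aggregate_folds <- function(fold_metrics) {
  stopifnot(length(fold_metrics) >= 1L)
  keys <- c("auroc", "auprc", "f1", "accuracy")
  per_fold <- as.data.frame(do.call(rbind, lapply(fold_metrics, function(m) {
    unlist(m[keys])
  })))
  per_fold$fold <- seq_len(nrow(per_fold))
  summary <- data.frame(
    metric = keys,
    mean = vapply(keys, function(k) mean(per_fold[[k]]), 1),
    sd = vapply(keys, function(k) stats::sd(per_fold[[k]]), 1)
  )
  if (nrow(per_fold) == 1L) summary$sd <- 0
  rownames(summary) <- NULL
  structure(list(per_fold = per_fold, summary = summary),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Metrics over", nrow(x$per_fold), "fold(s):\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-9s %.4f +/- %.4f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  invisible(x)
}
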