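#' Classification metrics for interaction scores
#'
#' AUC is computed as the Mann-Whitney pair statistic (tied scores count
#' 0.5), AUPR by step integration of the precision-recall curve over the
#' descending score thresholds, and accuracy / precision / recall at the
#' 0.5 threshold with scores equal to the threshold counted positive.
#' With a single-class label vector AUC and AUPR are undefined and returned
#' as \code{NA} (accuracy is still computed).
#'
#' @param scores Numeric prediction scores (higher = more likely positive).
#' @param labels 0/1 labels of the same length.
#' @return List of class \code{eval_metrics}: \code{auc}, \code{aupr},
#'   \code{accuracy}, \code{precision}, \code{recall}.
#' @examples
#' compute_metrics(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))  # AUC 0.75
#' @export
compute_metrics <- function(scores, labels) {
  if (length(scores) != length(labels) || length(scores) == 0L) {
    stop("invalid input: scores and labels must have equal positive length")
  }
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)

  if (npos == 0L || nneg == 0L) {
    auc <- NA_real_
    aupr <- NA_real_
  } else {
    r <- rank(scores, ties.method = "average")
    auc <- (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
    aupr <- .aupr_step(scores, labels, npos)
  }

  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  structure(list(
    auc = auc, aupr = aupr,
    accuracy = mean(pred == labels),
    precision = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0L) tp / (tp + fn) else NA_real_),
    class = "eval_metrics")
}

# PR step integration: thresholds at the distinct scores in descending
# order, tied scores entering as one block; AUPR = sum (R_i - R_{i-1}) * P_i
.aupr_step <- function(scores, labels, npos) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  block_last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[block_last]
  n_at <- block_last
  precision <- tp / n_at
  recall <- tp / npos
  sum(diff(c(0, recall)) * precision)
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "AUC %.4f  AUPR %.4f  accuracy %.4f  precision %.4f  recall %.4f\n",
    x$auc, x$aupr, x$accuracy, x$precision, x$recall))
  invisible(x)
}

#' Stratified train/test split
#'
#' Splits interaction pairs into disjoint, exhaustive train and test sets,
#' stratified by label; reproducible for a fixed seed (the caller's RNG
#' state is preserved).
#'
#' @param pairs data.frame with a 0/1 \code{label} column.
#' @param ratio Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return List with data.frames \code{train} and \code{test} and the
#'   corresponding row-index vectors \code{train_idx}, \code{test_idx}.
#' @export
split_dataset <- function(pairs, ratio = 0.8, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  n <- nrow(pairs)
  if (n < 5L) stop("invalid input: need at least 5 pairs")
  test_idx <- local_rng(seed, {
    unlist(lapply(split(seq_len(n), pairs$label), function(idx) {
      k <- round(length(idx) * (1 - ratio))
      sample(idx, k)
    }), use.names = FALSE)
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  list(train = pairs[train_idx, , drop = FALSE],
       test = pairs[test_idx, , drop = FALSE],
       train_idx = train_idx, test_idx = test_idx)
}

#' Stratified cross-validation folds
#'
#' @param labels 0/1 label vector.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector assigning each element to a fold \code{1..folds};
#'   fold sizes differ by at most one per class.
#' @export
make_cv_folds <- function(labels, folds = 5L, seed = 1L) {
  stopifnot(folds >= 2L)
  n <- length(labels)
  if (n < folds) stop("invalid input: fewer pairs than folds")
  assignment <- integer(n)
  local_rng(seed, {
    offset <- 0L
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      # continue the fold rotation across classes so that overall fold
      # sizes (not just per-class sizes) differ by at most one
      assignment[idx] <- ((seq_along(idx) - 1L + offset) %% folds) + 1L
      offset <- (offset + length(idx)) %% folds
    }
  })
  assignment
}
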