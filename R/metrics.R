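#' Ranking and threshold classification metrics
#'
#' Computes AUC (rank statistic with midrank tie handling), AUPR
#' (step-integrated precision-recall curve over the distinct score
#' thresholds), and accuracy, F1 and Matthews correlation at a fixed
#' threshold. AUC and AUPR are `NA` when only one class is present; MCC is
#' defined as 0 when its denominator vanishes.
#'
#' @param scores numeric vector of predicted scores.
#' @param labels 0/1 vector of the same length.
#' @param threshold decision threshold for ACC/F1/MCC; predictions are
#'   positive when `score >= threshold`. Default 0.5.
#' @return List with `auc`, `aupr`, `acc`, `f1`, `mcc`, and curve points
#'   `roc` (fpr, tpr) and `pr` (recall, precision).
#' @export
#' @examples
#' compute_metrics(c(0.9, 0.1, 0.8, 0.4), c(1, 0, 1, 0))
compute_metrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  auc <- aupr <- NA_real_
  roc <- pr <- NULL
  if (n1 > 0 && n0 > 0) {
    r <- rank(scores)                         # midranks on ties
    auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    ord <- order(scores, decreasing = TRUE)
    s_ord <- scores[ord]; y_ord <- labels[ord]
    grp_end <- which(!duplicated(s_ord, fromLast = TRUE))  # last idx per tie group
    tp <- cumsum(y_ord)[grp_end]
    npred <- grp_end
    prec <- tp / npred
    rec <- tp / n1
    fpr <- (npred - tp) / n0
    aupr <- sum(diff(c(0, rec)) * prec)
    roc <- data.frame(fpr = c(0, fpr), tpr = c(0, rec))
    pr <- data.frame(recall = rec, precision = prec)
  }
  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1 & labels == 1); TN <- sum(pred == 0 & labels == 0)
  FP <- sum(pred == 1 & labels == 0); FN <- sum(pred == 0 & labels == 1)
  acc <- (TP + TN) / length(labels)
  f1 <- if (2 * TP + FP + FN == 0) 0 else 2 * TP / (2 * TP + FP + FN)
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (den == 0) 0 else (TP * TN - FP * FN) / den
  list(auc = auc, aupr = aupr, acc = acc, f1 = f1, mcc = mcc,
       roc = roc, pr = pr)
}

#' Stratified fold assignment for cross-validation
#'
#' Shuffles the known positive pairs and assigns them round-robin to
#' `n_folds` folds (fold sizes differ by at most one). For each fold a
#' balanced test-negative set of equal size is drawn without replacement
#' from the candidate pool, disjoint across folds when the pool allows;
#' otherwise per-fold draws are independent (non-disjoint) with a warning.
#'
#' @param positives two-column integer matrix of known (drug, microbe)
#'   index pairs.
#' @param n_folds number of folds, default 5.
#' @param negatives_pool two-column matrix of candidate negative pairs.
#' @param seed optional integer seed.
#' @return Object of class `"fold_split"`: list with `positives`, `fold`
#'   (fold id per positive), `test_negatives` (list of matrices), `n_folds`.
#' @export
kfold_split <- function(positives, n_folds = 5, negatives_pool, seed = NULL) {
  positives <- as.matrix(positives)
  np <- nrow(positives)
  if (np < n_folds) {
    stop("need at least as many positives as folds", call. = FALSE)
  }
  with_seed(seed, {
    fold <- integer(np)
    fold[sample.int(np)] <- rep(seq_len(n_folds), length.out = np)
    sizes <- tabulate(fold, n_folds)
    negs <- vector("list", n_folds)
    pool_n <- nrow(negatives_pool)
    if (pool_n >= np) {
      picks <- sample.int(pool_n, np)
      off <- 0L
      for (f in seq_len(n_folds)) {
        negs[[f]] <- negatives_pool[picks[off + seq_len(sizes[f])], ,
                                    drop = FALSE]
        off <- off + sizes[f]
      }
    } else {
      warning("candidate pool too small for disjoint balanced negatives; ",
              "drawing per fold independently")
      for (f in seq_len(n_folds)) {
        negs[[f]] <- negatives_pool[sample.int(pool_n, min(sizes[f], pool_n)), ,
                                    drop = FALSE]
      }
    }
    structure(list(positives = positives, fold = fold,
                   test_negatives = negs, n_folds = n_folds),
              class = "fold_split")
  })
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("%d-fold split of %d positives (fold sizes: %s)\n",
              x$n_folds, nrow(x$positives),
              paste(tabulate(x$fold, x$n_folds), collapse = ", ")))
  invisible(x)
}
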