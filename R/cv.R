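#' 5-fold cross-validation of the association model
#'
#' Splits the known positives into folds, masks each fold's positives out of
#' the training adjacency, refits the model on the masked table, scores the
#' fold's balanced test set (the held-out positives plus an equal number of
#' seeded test negatives), and aggregates ranking and threshold metrics as
#' mean and standard deviation over folds.
#'
#' By default (`similarity_scope = "train_only"`) the GIP similarities are
#' recomputed inside each fold from the training-masked adjacency, so no
#' information about test positives can leak through the kernel;
#' `"full"` computes them once from the complete table (the optimistic
#' alternative). Masked test positives remain zeros in the training table
#' and are therefore eligible as sampled training negatives — the realistic
#' regime, since the trainer has no access to test labels; set
#' `exclude_test_pairs = TRUE` to remove all test pairs from the candidate
#' pool instead.
#'
#' @inheritParams mdassoc
#' @param n_folds number of folds, default 5.
#' @param similarity_scope `"train_only"` (leakage-free, default) or
#'   `"full"`.
#' @param exclude_test_pairs drop the fold's test pairs from the training
#'   candidate-negative pool.
#' @param keep_fits store each fold's training table and score matrix in
#'   the result (memory permitting); each fold's fit is reproducible as
#'   `mdassoc(train_table, ..., seed = fold_seeds[f])`, which makes it
#'   checkable that fold training depends on nothing but the masked
#'   training data.
#' @return Object of class `"mdassoc_cv"`: list with `metrics` (per-fold
#'   data frame of auc/aupr/acc/f1/mcc), `mean`, `sd`, `split` (the
#'   [kfold_split()]), `fold_seeds`, `control`.
#' @export
mdassoc_cv <- function(assoc, drug_sim = NULL, microbe_sim = NULL,
                       n_folds = 5, control = mdassoc_control(),
                       seed = NULL,
                       similarity_scope = c("train_only", "full"),
                       exclude_test_pairs = FALSE, keep_fits = FALSE) {
  stopifnot(inherits(assoc, "association_table"))
  similarity_scope <- match.arg(similarity_scope)
  A <- assoc$A
  positives <- which(A == 1, arr.ind = TRUE); dimnames(positives) <- NULL
  pool <- which(A == 0, arr.ind = TRUE); dimnames(pool) <- NULL
  with_seed(seed, {
    split <- kfold_split(positives, n_folds, pool)
    fold_seeds <- sample.int(.Machine$integer.max, n_folds)
    full_sim <- NULL
    if (similarity_scope == "full") {
      full_sim <- list(
        drug = integrate_similarity(
          gip_similarity(A, control$raw_bandwidth), drug_sim),
        microbe = integrate_similarity(
          gip_similarity(t(A), control$raw_bandwidth), microbe_sim))
    }
    rows <- vector("list", n_folds)
    fold_fits <- if (keep_fits) vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      test_pos <- split$positives[split$fold == f, , drop = FALSE]
      test_neg <- split$test_negatives[[f]]
      A_train <- A
      A_train[test_pos] <- 0
      assoc_train <- association_table(A_train, assoc$drug_ids,
                                       assoc$microbe_ids)
      excl <- if (exclude_test_pairs) rbind(test_pos, test_neg) else NULL
      fit <- mdassoc(assoc_train, drug_sim, microbe_sim, control,
                     seed = fold_seeds[f], similarity = full_sim,
                     excluded_pairs = excl)
      if (keep_fits) {
        fold_fits[[f]] <- list(train = assoc_train, scores = fit$scores)
      }
      test_pairs <- rbind(test_pos, test_neg)
      labels <- c(rep(1, nrow(test_pos)), rep(0, nrow(test_neg)))
      scores <- fit$scores[test_pairs]
      if (length(unique(labels)) < 2L) {
        warning(sprintf("fold %d has a degenerate test set; excluded", f))
        next
      }
      m <- compute_metrics(scores, labels)
      rows[[f]] <- data.frame(fold = f, auc = m$auc, aupr = m$aupr,
                              acc = m$acc, f1 = m$f1, mcc = m$mcc)
    }
    metrics <- do.call(rbind, rows)
    cols <- c("auc", "aupr", "acc", "f1", "mcc")
    structure(list(metrics = metrics,
                   mean = colMeans(metrics[cols]),
                   sd = apply(metrics[cols], 2, stats::sd),
                   split = split, fold_seeds = fold_seeds,
                   fold_fits = if (keep_fits) fold_fits,
                   control = control, seed = seed,
                   similarity_scope = similarity_scope),
              class = "mdassoc_cv")
  })
}

#' @export
print.mdassoc_cv <- function(x, digits = 4, ...) {
  cat(sprintf("%d-fold cross-validation (%s similarities, sampler = %s)\n",
              x$split$n_folds, x$similarity_scope, x$control$sampler))
  for (m in names(x$mean)) {
    cat(sprintf("  %-5s %.*f ∓ %.*f\n", toupper(m), digits, x$mean[[m]],
                digits, x$sd[[m]]))
  }
  invisible(x)
}

#' Rank candidate microbes for a target drug
#'
#' Sorts the microbes by descending predicted score for one drug, breaking
#' ties by microbe identifier so the ranking is deterministic. Known
#' training associations of the drug can be masked from the list.
#'
#' @param object an `"mdassoc"` fit, or a score matrix with identifier
#'   dimnames.
#' @param target drug identifier (row name of the score matrix).
#' @param top_n how many microbes to return (default 20; clamped to the
#'   number available).
#' @param mask_known drop microbes already associated with the drug in the
#'   training table (only available when `object` is a fit).
#' @return Data frame with `rank`, `microbe`, `score`.
#' @export
rank_candidates <- function(object, target, top_n = 20, mask_known = FALSE) {
  scores <- if (inherits(object, "mdassoc")) object$scores else as.matrix(object)
  if (!target %in% rownames(scores)) {
    near <- utils::head(agrep(target, rownames(scores), value = TRUE,
                              max.distance = 0.3), 5)
    stop("unknown drug identifier: ", target,
         if (length(near)) paste0("; did you mean: ",
                                  paste(near, collapse = ", "), "?") else "",
         call. = FALSE)
  }
  s <- scores[target, ]
  if (mask_known) {
    if (!inherits(object, "mdassoc")) {
      stop("mask_known requires a fitted model object", call. = FALSE)
    }
    s <- s[object$assoc$A[target, ] == 0]
  }
  ord <- order(-s, names(s))
  take <- utils::head(ord, top_n)
  data.frame(rank = seq_along(take), microbe = names(s)[take],
             score = unname(s[take]), row.names = NULL)
}
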