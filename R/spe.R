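#' Hardness of a scored sample
#'
#' Squared error between a classifier score and the binary label,
#' `H = (score - label)^2`, always in \[0, 1\] for sigmoid scores. For a
#' candidate negative (label 0), high hardness flags a likely false negative
#' ("noise"), low hardness a well-learned trivial sample, and mid-range
#' hardness the informative boundary samples.
#'
#' @param predicted_score score(s) in (0, 1).
#' @param label binary label(s), recycled against the scores.
#' @return Hardness value(s) in \[0, 1\].
#' @export
spe_hardness <- function(predicted_score, label) {
  (predicted_score - label)^2
}

#' Assign hardness values to buckets
#'
#' Bucket `l` covers hardness `[(l-1)/k, l/k)`, with the last bucket closed
#' at 1: `l = min(floor(H * k) + 1, k)`. The half-open convention resolves
#' the boundary ties left ambiguous by overlapping closed intervals.
#'
#' @param hardness_values numeric vector in \[0, 1\].
#' @param k number of buckets (>= 1).
#' @return Integer bucket index per sample, in `1..k`.
#' @export
spe_assign_buckets <- function(hardness_values, k) {
  stopifnot(k >= 1)
  if (any(hardness_values < 0 | hardness_values > 1)) {
    stop("hardness values must lie in [0, 1]", call. = FALSE)
  }
  pmin(floor(hardness_values * k) + 1L, as.integer(k))
}

#' Self-paced factor schedule
#'
#' `beta = -log((n - i) / n)` for iteration `i` in `0..n-1` of an `n`-epoch
#' run: zero at the first iteration, strictly increasing, and naturally
#' clamped at `-log(1/n)` on the final iteration. Growing `beta` flattens
#' the bucket weights, shifting sampling mass from easy toward hard
#' negatives as training proceeds.
#'
#' @param iteration current iteration `i`, 0-based.
#' @param total_epochs total number of training epochs `n` (> `iteration`).
#' @return Non-negative scalar `beta`.
#' @export
spe_self_paced_factor <- function(iteration, total_epochs) {
  stopifnot(iteration >= 0, total_epochs >= 1)
  if (iteration >= total_epochs) {
    stop("iteration must be smaller than total_epochs", call. = FALSE)
  }
  -log((total_epochs - iteration) / total_epochs)
}

#' Normalized bucket sampling weights
#'
#' `W_l = 1 / (h_l + beta)` for non-empty buckets, 0 for empty ones
#' (signalled by `NA` mean hardness), normalized to sum 1. A floor of
#' `1e-12` on the denominator guards the `h_l = beta = 0` start.
#'
#' @param mean_hardness per-bucket mean hardness; `NA` marks an empty bucket.
#' @param beta self-paced factor (>= 0).
#' @return Normalized weight vector, zeros on empty buckets.
#' @export
spe_bucket_weights <- function(mean_hardness, beta) {
  stopifnot(beta >= 0)
  if (all(is.na(mean_hardness))) {
    stop("all buckets are empty; cannot form sampling weights", call. = FALSE)
  }
  w <- ifelse(is.na(mean_hardness), 0, 1 / pmax(mean_hardness + beta, 1e-12))
  w / sum(w)
}

#' Allocate per-bucket sample counts
#'
#' Real-valued targets `W_l * |P|` are rounded by largest remainder so the
#' counts sum to `|P|` exactly; any count exceeding its bucket size is
#' capped and the surplus redistributed proportionally among the un-capped
#' buckets, iterated to a fixpoint. The total falls below `|P|` only when
#' the whole pool is smaller than `|P|`. Remainder ties break toward the
#' lower bucket index.
#'
#' @param weights normalized weight vector (zeros allowed).
#' @param positives_count target total `|P|`.
#' @param bucket_sizes per-bucket candidate counts.
#' @return Integer allocation vector summing to
#'   `min(positives_count, sum(bucket_sizes[weights > 0]))`.
#' @export
spe_allocate_counts <- function(weights, positives_count, bucket_sizes) {
  k <- length(weights)
  stopifnot(length(bucket_sizes) == k, positives_count >= 0)
  alloc <- integer(k)
  remaining <- min(positives_count, sum(bucket_sizes[weights > 0]))
  repeat {
    open <- which(weights > 0 & alloc < bucket_sizes)
    if (remaining <= 0 || length(open) == 0L) break
    w <- weights[open] / sum(weights[open])
    tgt <- w * remaining
    n <- floor(tgt)
    short <- remaining - sum(n)
    if (short > 0) {
      ord <- order(tgt - n, decreasing = TRUE)  # stable: ties to lower index
      n[ord[seq_len(short)]] <- n[ord[seq_len(short)]] + 1
    }
    add <- pmin(n, bucket_sizes[open] - alloc[open])
    alloc[open] <- alloc[open] + as.integer(add)
    remaining <- remaining - sum(add)
    if (sum(add) == 0) break
  }
  alloc
}

#' Draw one self-paced negative sample set
#'
#' Composes the full per-iteration pipeline: hardness of every candidate
#' negative under the current scores, k-bucket partition, self-paced factor
#' for this iteration, inverse-hardness bucket weights, largest-remainder
#' allocation, and uniform without-replacement sampling inside each bucket.
#'
#' @param pool two-column integer matrix of candidate negative pairs
#'   (drug index, microbe index).
#' @param scores predicted scores for the pool rows, in (0, 1).
#' @param k bucket count.
#' @param iteration,total_epochs schedule position (see
#'   [spe_self_paced_factor()]).
#' @param positives_count number of training positives `|P|`; defaults to
#'   the pool size cap.
#' @return Matrix of selected pool rows; attribute `"diagnostics"` carries
#'   `beta`, per-bucket mean hardness, weights, sizes and allocations.
#' @export
spe_sample_iteration <- function(pool, scores, k, iteration, total_epochs,
                                 positives_count) {
  pool <- as.matrix(pool)
  if (nrow(pool) != length(scores)) {
    stop("scores must align with the candidate pool", call. = FALSE)
  }
  H <- spe_hardness(scores, 0)
  bucket <- spe_assign_buckets(H, k)
  sizes <- tabulate(bucket, nbins = k)
  hbar <- rep(NA_real_, k)
  occ <- sizes > 0
  hs <- vapply(split(H, factor(bucket, levels = seq_len(k))), function(v) {
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  hbar[occ] <- hs[occ]
  beta <- spe_self_paced_factor(iteration, total_epochs)
  w <- spe_bucket_weights(hbar, beta)
  alloc <- spe_allocate_counts(w, positives_count, sizes)
  picks <- integer(0)
  for (l in which(alloc > 0)) {
    members <- which(bucket == l)
    picks <- c(picks, members[sample.int(length(members), alloc[l])])
  }
  out <- pool[picks, , drop = FALSE]
  attr(out, "diagnostics") <- list(beta = beta, mean_hardness = hbar,
                                   weights = w, sizes = sizes,
                                   allocations = alloc)
  out
}

#' Uniform random undersample of the candidate pool
#'
#' Bootstrap step for the first training epoch, before any predictions
#' exist: a uniform without-replacement draw of `min(|P|, |pool|)` candidate
#' negatives.
#'
#' @inheritParams spe_sample_iteration
#' @return Matrix of selected pool rows.
#' @export
initial_random_undersample <- function(pool, positives_count) {
  pool <- as.matrix(pool)
  if (nrow(pool) == 0L) {
    stop("candidate pool is empty; cannot draw negatives", call. = FALSE)
  }
  n <- min(positives_count, nrow(pool))
  if (n < positives_count) {
    warning(sprintf("pool (%d) smaller than positives (%d); drawing %d",
                    nrow(pool), positives_count, n))
  }
  pool[sample.int(nrow(pool), n), , drop = FALSE]
}
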