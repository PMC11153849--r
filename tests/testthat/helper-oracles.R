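# Independent brute-force oracles. Everything here is written as plain
# loops or exhaustive enumeration, deliberately avoiding the vectorized
# code paths in the package.

oracle_gip <- function(A, raw_bandwidth = 1) {
  n <- nrow(A)
  mu <- raw_bandwidth / mean(sapply(seq_len(n), function(i) sum(A[i, ]^2)))
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      S[i, j] <- exp(-mu * sum((A[i, ] - A[j, ])^2))
    }
  }
  S
}

# Per-node loop version of the neighborhood pre-convolution.
oracle_convolve <- function(X, graph, lambda2) {
  out <- X * 0
  for (i in seq_len(nrow(X))) {
    nb <- setdiff(graph$nbrs[[i]], i)
    acc <- X[i, ]
    for (j in nb) acc <- acc + lambda2 * X[j, ]
    out[i, ] <- acc / (1 + lambda2 * length(nb))
  }
  out
}

# Plain single-head graph-attention layer (attention over raw features),
# identity activation; per-node/per-edge loops throughout.
oracle_gat <- function(X, W, a, slope, graph) {
  H <- X %*% W
  dout <- ncol(H)
  n <- nrow(X)
  out <- matrix(0, n, dout)
  for (i in seq_len(n)) {
    nb <- graph$nbrs[[i]]
    e <- numeric(length(nb))
    for (t in seq_along(nb)) {
      u <- sum(a * c(H[i, ], H[nb[t], ]))
      e[t] <- if (u > 0) u else slope * u
    }
    w <- exp(e - max(e)); w <- w / sum(w)
    for (t in seq_along(nb)) out[i, ] <- out[i, ] + w[t] * H[nb[t], ]
  }
  out
}

# Threshold-enumeration metrics oracle: AUC by pair counting with half
# credit on ties; AUPR by walking every distinct threshold.
oracle_metrics <- function(scores, labels, threshold = 0.5) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  auc <- aupr <- NA_real_
  if (length(pos) > 0 && length(neg) > 0) {
    tot <- 0
    for (i in pos) {
      for (j in neg) {
        tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
      }
    }
    auc <- tot / (length(pos) * length(neg))
    thr <- sort(unique(scores), decreasing = TRUE)
    prev_rec <- 0; aupr <- 0
    for (t in thr) {
      sel <- scores >= t
      tp <- sum(sel & labels == 1)
      prec <- tp / sum(sel)
      rec <- tp / length(pos)
      aupr <- aupr + (rec - prev_rec) * prec
      prev_rec <- rec
    }
  }
  pred <- as.integer(scores >= threshold)
  TP <- sum(pred & labels); TN <- sum(!pred & !labels)
  FP <- sum(pred & !labels); FN <- sum(!pred & labels)
  f1 <- if (2 * TP + FP + FN == 0) 0 else 2 * TP / (2 * TP + FP + FN)
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  list(auc = auc, aupr = aupr, acc = (TP + TN) / length(labels), f1 = f1,
       mcc = if (den == 0) 0 else (TP * TN - FP * FN) / den)
}

# Literal largest-remainder allocation with cap-and-redistribute, iterated
# to a fixpoint, written step by step.
oracle_allocate <- function(weights, P, sizes) {
  k <- length(weights)
  alloc <- rep(0, k)
  capped <- rep(FALSE, k)
  target_total <- min(P, sum(sizes[weights > 0]))
  repeat {
    todo <- target_total - sum(alloc)
    open <- which(!capped & weights > 0 & sizes > 0)
    if (todo <= 0 || length(open) == 0) break
    w <- weights[open] / sum(weights[open])
    real <- w * todo
    base <- floor(real)
    extra <- todo - sum(base)
    if (extra > 0) {
      ord <- open[order(real - base, decreasing = TRUE)]
      for (b in ord[seq_len(extra)]) {
        base[match(b, open)] <- base[match(b, open)] + 1
      }
    }
    progressed <- FALSE
    for (t in seq_along(open)) {
      l <- open[t]
      room <- sizes[l] - alloc[l]
      give <- min(base[t], room)
      alloc[l] <- alloc[l] + give
      if (give > 0) progressed <- TRUE
      if (alloc[l] >= sizes[l]) capped[l] <- TRUE
    }
    if (!progressed) break
  }
  alloc
}

with_seed_draw <- function(seed, expr) {
  set.seed(seed)
  expr
}

random_assoc <- function(nd, nm, density = 0.3) {
  A <- matrix(rbinom(nd * nm, 1, density), nd, nm)
  # GIP needs at least one nonzero profile on each side
  if (sum(A) == 0) A[sample(nd, 1), sample(nm, 1)] <- 1
  association_table(A)
}

random_graph <- function(n, p = 0.5) {
  Y <- matrix(runif(n * n), n, n)
  Y <- (Y + t(Y)) / 2
  Y[Y < p] <- 0
  diag(Y) <- 1
  graph_neighborhoods(Y)
}
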