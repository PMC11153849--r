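#' MLP decoder parameters
#'
#' The decoder scores a (drug, microbe) pair from the elementwise product of
#' their embeddings: `score = sigmoid(W2 %*% relu(W1 %*% (E_m * E_d)))` with
#' `W1` an `F x F` matrix and `W2` a length-`F` vector. Weights are
#' Glorot-uniform initialized from the ambient RNG stream.
#'
#' @param embedding_dim embedding width `F`.
#' @return List of class `"mlp_decoder"` with `W1` (`F x F`) and `W2`
#'   (length `F`).
#' @export
mlp_decoder <- function(embedding_dim) {
  s1 <- sqrt(6 / (2 * embedding_dim))
  s2 <- sqrt(6 / (embedding_dim + 1))
  structure(list(
    W1 = matrix(stats::runif(embedding_dim^2, -s1, s1),
                embedding_dim, embedding_dim),
    W2 = stats::runif(embedding_dim, -s2, s2),
    embedding_dim = embedding_dim), class = "mlp_decoder")
}

#' Score one drug-microbe pair
#'
#' @param drug_embedding,microbe_embedding numeric vectors of length `F`.
#' @param params an [mlp_decoder()].
#' @return Scalar score strictly in (0, 1).
#' @export
#' @examples
#' dec <- list(W1 = diag(2), W2 = c(1, 1), embedding_dim = 2)
#' mlp_score(c(1, 1), c(1, 2), dec)  # sigmoid(3)
mlp_score <- function(drug_embedding, microbe_embedding, params) {
  F_ <- params$embedding_dim %||% length(params$W2)
  if (length(drug_embedding) != F_ || length(microbe_embedding) != F_) {
    stop_dims("mlp_score embeddings",
              c(length(drug_embedding), length(microbe_embedding)), c(F_, F_))
  }
  p <- drug_embedding * microbe_embedding
  h <- pmax(drop(params$W1 %*% p), 0)
  sigmoid(sum(params$W2 * h))
}

# Batched decoder forward over explicit (drug row, microbe row) index pairs
# into the embedding matrix. Returns scores and, optionally, the tensors
# needed for the backward pass.
decoder_forward <- function(E, idx_drug, idx_microbe, params,
                            return_cache = FALSE) {
  P <- E[idx_drug, , drop = FALSE] * E[idx_microbe, , drop = FALSE]
  Hpre <- P %*% t(params$W1)
  H <- pmax(Hpre, 0)
  s <- sigmoid(drop(H %*% params$W2))
  if (!return_cache) return(s)
  list(s = s, cache = list(P = P, Hpre = Hpre, H = H,
                           idx_drug = idx_drug, idx_microbe = idx_microbe))
}

# Backward for sigmoid + binary cross entropy: d(loss)/d(pre-sigmoid) is
# (s - z) (scaled by 1/B for mean reduction). Returns decoder gradients and
# the gradient accumulated into the embedding matrix rows.
decoder_backward <- function(E, cache, params, s, z, scale = 1) {
  dpre <- (s - z) * scale
  gW2 <- drop(crossprod(cache$H, dpre))
  dH <- outer(dpre, params$W2)
  dHpre <- dH * (cache$Hpre > 0)
  gW1 <- crossprod(dHpre, cache$P)
  dP <- dHpre %*% params$W1
  dE <- matrix(0, nrow(E), ncol(E))
  dEd <- rowsum(dP * E[cache$idx_microbe, , drop = FALSE], cache$idx_drug)
  dEm <- rowsum(dP * E[cache$idx_drug, , drop = FALSE], cache$idx_microbe)
  dE[as.integer(rownames(dEd)), ] <- dE[as.integer(rownames(dEd)), ] + dEd
  dE[as.integer(rownames(dEm)), ] <- dE[as.integer(rownames(dEm)), ] + dEm
  list(gW1 = gW1, gW2 = gW2, dE = dE)
}

#' Score every drug-microbe pair
#'
#' Applies the decoder to all `Nd x Nm` embedding pairs, with drugs in
#' embedding rows `1..Nd` and microbes in rows `Nd+1..Nd+Nm`.
#'
#' @param embeddings embedding matrix `E` (`(Nd+Nm) x F`).
#' @param nd,nm block sizes (drugs, microbes).
#' @param params an [mlp_decoder()].
#' @return `Nd x Nm` score matrix with entries strictly in (0, 1).
#' @export
score_all_pairs <- function(embeddings, nd, nm, params) {
  stopifnot(nrow(embeddings) == nd + nm)
  idx_d <- rep(seq_len(nd), times = nm)
  idx_m <- rep(nd + seq_len(nm), each = nd)
  s <- decoder_forward(embeddings, idx_d, idx_m, params)
  matrix(s, nd, nm)
}

#' Binary cross-entropy loss
#'
#' `L = -sum(z * log(s) + (1 - z) * log(1 - s))` over the sample set, with
#' scores clipped to `[eps, 1 - eps]` before the logs. The reported training
#' loss is the sum; a mean reduction is available for optimizer scaling.
#'
#' @param scores numeric vector of predicted scores in (0, 1).
#' @param labels 0/1 vector of the same length.
#' @param reduction `"sum"` (default) or `"mean"`.
#' @param eps clipping constant, default `1e-7`.
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(scores, labels, reduction = c("sum", "mean"),
                     eps = 1e-7) {
  reduction <- match.arg(reduction)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  s <- clip01(scores, eps)
  ll <- -(labels * log(s) + (1 - labels) * log(1 - s))
  if (reduction == "sum") sum(ll) else mean(ll)
}
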