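#' Learnable graph convolutional attention layer
#'
#' One encoder layer holds a weight matrix `W` (`in_dim x out_dim`), an
#' attention vector `a` (length `2 * out_dim`), and two interpolation
#' scalars. `lambda1` gates the attention mechanism and `lambda2` gates a
#' neighborhood pre-convolution of the features, so a single layer moves
#' continuously between three classical behaviours:
#' uniform neighbor averaging (`lambda1 = 0`), plain graph attention
#' (`lambda1 = 1, lambda2 = 0`), and attention over pre-convolved features
#' (`lambda1 = lambda2 = 1`). In `"free"` mode both scalars are trainable
#' through a sigmoid of an unconstrained raw value (initialized at 0, i.e.
#' mid-interpolation 0.5); the named modes freeze them at the corresponding
#' corner.
#'
#' @param in_dim,out_dim layer widths.
#' @param leaky_slope negative slope of the LeakyReLU inside the attention
#'   score, default 0.2.
#' @param lambda_mode one of `"free"`, `"gcn"`, `"gat"`, `"cat"`, `"fixed"`.
#' @param lambda1,lambda2 fixed values used when `lambda_mode = "fixed"`.
#' @return A list of class `"lcat_layer"` with the parameters and
#'   trainability flags.
#' @export
lcat_layer <- function(in_dim, out_dim, leaky_slope = 0.2,
                       lambda_mode = c("free", "gcn", "gat", "cat", "fixed"),
                       lambda1 = 0.5, lambda2 = 0.5) {
  lambda_mode <- match.arg(lambda_mode)
  sW <- sqrt(6 / (in_dim + out_dim))
  sa <- sqrt(6 / (2 * out_dim + 1))
  layer <- list(
    W = matrix(stats::runif(in_dim * out_dim, -sW, sW), in_dim, out_dim),
    a = stats::runif(2 * out_dim, -sa, sa),
    lambda1_raw = 0, lambda2_raw = 0,
    lambda_fixed = c(NA_real_, NA_real_),
    train_l1 = FALSE, train_l2 = FALSE,
    leaky_slope = leaky_slope, lambda_mode = lambda_mode,
    in_dim = in_dim, out_dim = out_dim)
  switch(lambda_mode,
    free  = { layer$train_l1 <- TRUE; layer$train_l2 <- TRUE },
    gcn   = { layer$lambda_fixed[1] <- 0; layer$train_l2 <- TRUE },
    gat   = { layer$lambda_fixed <- c(1, 0) },
    cat   = { layer$lambda_fixed <- c(1, 1) },
    fixed = { layer$lambda_fixed <- c(lambda1, lambda2) })
  class(layer) <- "lcat_layer"
  layer
}

#' Interpolation coefficients of a layer
#'
#' @param layer an `"lcat_layer"`.
#' @return Numeric `c(lambda1, lambda2)`, both in \[0, 1\].
#' @export
layer_lambdas <- function(layer) {
  l1 <- if (is.na(layer$lambda_fixed[1])) sigmoid(layer$lambda1_raw) else layer$lambda_fixed[1]
  l2 <- if (is.na(layer$lambda_fixed[2])) sigmoid(layer$lambda2_raw) else layer$lambda_fixed[2]
  c(lambda1 = l1, lambda2 = l2)
}

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)
elu <- function(x) ifelse(x > 0, x, expm1(x))

#' Neighborhood pre-convolution of node features
#'
#' For each node, blends its own feature row with the sum of its neighbors'
#' rows: `conv_i = (X_i + lambda2 * sum_{j in N(i), j != i} X_j) /
#' (1 + lambda2 * |N(i) \ i|)`. `lambda2 = 0` returns the features
#' unchanged; `lambda2 = 1` is a plain mean over the closed neighborhood.
#'
#' @param features node-feature matrix, one row per node.
#' @param graph an `"lcat_graph"`.
#' @param lambda2 convolution strength in \[0, 1\].
#' @return Matrix of the same shape as `features`.
#' @export
convolve_features <- function(features, graph, lambda2) {
  features <- as.matrix(features)
  if (nrow(features) != graph$n) {
    stop_dims("convolve_features", nrow(features), graph$n)
  }
  if (lambda2 == 0) return(features)
  S <- graph$adj %*% features          # neighbor sums, self excluded
  denom <- 1 + lambda2 * graph$deg
  (features + lambda2 * S) / denom     # row-wise division
}

#' Per-edge attention logits
#'
#' `logit[i, j] = lambda1 * LeakyReLU(a' [W conv_i || W conv_j])`, computed
#' densely for all ordered node pairs; only entries inside a node's
#' neighborhood (self-loop included) are meaningful and used downstream.
#'
#' @param conv_features pre-convolved node features.
#' @param params an `"lcat_layer"`.
#' @param graph an `"lcat_graph"` (shape check only).
#' @return Dense `n x n` matrix of logits.
#' @export
attention_logits <- function(conv_features, params, graph) {
  conv_features <- as.matrix(conv_features)
  if (ncol(conv_features) != nrow(params$W)) {
    stop_dims("attention_logits features", ncol(conv_features), nrow(params$W))
  }
  if (length(params$a) != 2 * ncol(params$W)) {
    stop_dims("attention vector", length(params$a), 2 * ncol(params$W))
  }
  lam <- layer_lambdas(params)
  H <- conv_features %*% params$W
  dout <- ncol(H)
  f <- drop(H %*% params$a[seq_len(dout)])
  g <- drop(H %*% params$a[dout + seq_len(dout)])
  U <- outer(f, rep(1, length(g))) + outer(rep(1, length(f)), g)
  lam[1] * leaky_relu(U, params$leaky_slope)
}

#' Softmax-normalize attention logits over each neighborhood
#'
#' `rho[i, j] = exp(logit[i, j]) / sum_{k in N(i)} exp(logit[i, k])`,
#' computed with per-row max subtraction for stability; entries outside the
#' neighborhood are exactly 0 and each row sums to 1.
#'
#' @param logits dense logits matrix (as from [attention_logits()]).
#' @param graph an `"lcat_graph"` supplying the neighborhood mask.
#' @return Dense `n x n` matrix of attention weights.
#' @export
normalize_attention <- function(logits, graph) {
  E <- as.matrix(logits)
  E[!graph$mask] <- -Inf
  rmax <- apply(E, 1L, max)
  P <- exp(E - rmax)
  P[!graph$mask] <- 0
  P / rowSums(P)
}

#' Forward pass of one encoder layer
#'
#' Pre-convolves features, computes attention weights, and aggregates:
#' `out_i = act(sum_{j in N(i)} rho[i, j] * (W conv_j))` with an ELU
#' activation between layers and identity at the final layer.
#'
#' @inheritParams attention_logits
#' @param features raw node features entering the layer.
#' @param activation `"elu"` or `"identity"`.
#' @param return_cache keep intermediate tensors for the backward pass.
#' @return Output feature matrix (`n x out_dim`); with `return_cache = TRUE`
#'   a list `(out, cache)`.
#' @export
lcat_layer_forward <- function(features, params, graph,
                               activation = c("elu", "identity"),
                               return_cache = FALSE) {
  activation <- match.arg(activation)
  X <- as.matrix(features)
  lam <- layer_lambdas(params)
  S <- graph$adj %*% X
  denom <- 1 + lam[2] * graph$deg
  Xt <- (X + lam[2] * S) / denom
  H <- Xt %*% params$W
  dout <- ncol(H)
  f <- drop(H %*% params$a[seq_len(dout)])
  g <- drop(H %*% params$a[dout + seq_len(dout)])
  U <- outer(f, rep(1, graph$n)) + outer(rep(1, graph$n), g)
  Lr <- leaky_relu(U, params$leaky_slope)
  logits <- lam[1] * Lr
  rho <- normalize_attention(logits, graph)
  Z <- rho %*% H
  out <- if (activation == "elu") elu(Z) else Z
  if (!return_cache) return(out)
  list(out = out,
       cache = list(X = X, S = S, denom = denom, Xt = Xt, H = H, U = U,
                    Lr = Lr, rho = rho, Z = Z, out = out, lam = lam,
                    activation = activation))
}

# Analytic backward pass of one layer. `dOut` is the loss gradient at the
# layer output; returns the gradient at the layer input plus parameter
# gradients (raw-scale for the interpolation scalars, zero when frozen).
lcat_layer_backward <- function(cache, params, graph, dOut) {
  lam <- cache$lam
  dZ <- if (cache$activation == "elu") {
    dOut * ifelse(cache$Z > 0, 1, cache$out + 1)
  } else dOut
  dRho <- dZ %*% t(cache$H)
  dRho[!graph$mask] <- 0
  dH <- crossprod(cache$rho, dZ)
  rs <- rowSums(cache$rho * dRho)
  dLogit <- cache$rho * (dRho - rs)
  dl1 <- sum(dLogit * cache$Lr)
  dU <- dLogit * (lam[1] * ifelse(cache$U > 0, 1, params$leaky_slope))
  df <- rowSums(dU)
  dg <- colSums(dU)
  dout <- ncol(cache$H)
  a1 <- params$a[seq_len(dout)]
  a2 <- params$a[dout + seq_len(dout)]
  dH <- dH + outer(df, a1) + outer(dg, a2)
  da <- c(drop(crossprod(cache$H, df)), drop(crossprod(cache$H, dg)))
  dW <- crossprod(cache$Xt, dH)
  dXt <- dH %*% t(params$W)
  dT <- dXt / cache$denom
  dX <- dT + lam[2] * crossprod(graph$adj, dT)
  dl2 <- sum(dXt * ((cache$S - graph$deg * cache$Xt) / cache$denom))
  list(dX = dX, gW = dW, ga = da,
       gl1raw = if (params$train_l1) dl1 * lam[1] * (1 - lam[1]) else 0,
       gl2raw = if (params$train_l2) dl2 * lam[2] * (1 - lam[2]) else 0)
}

#' Encode network nodes into embeddings
#'
#' Stacks encoder layers over the node features (the rows of the network
#' matrix `Y`), applying ELU between layers and identity after the last.
#' During training an inverted-dropout mask is applied to each layer's
#' input.
#'
#' @param features node-feature matrix, typically `net$Y` (drugs first, then
#'   microbes); a `"hetnet"` is accepted directly.
#' @param layers list of `"lcat_layer"` objects with chained widths.
#' @param graph an `"lcat_graph"`.
#' @param dropout input dropout rate used when `training = TRUE`.
#' @param training logical; enables dropout (stochastic, draws from the
#'   ambient RNG stream).
#' @param return_cache keep per-layer caches for the backward pass.
#' @return Embedding matrix `E` (`n x F`), rows in the network's node order;
#'   with `return_cache = TRUE` a list `(E, caches, masks)`.
#' @export
lcat_encode <- function(features, layers, graph, dropout = 0,
                        training = FALSE, return_cache = FALSE) {
  if (inherits(features, "hetnet")) features <- features$Y
  X <- as.matrix(features)
  nl <- length(layers)
  caches <- vector("list", nl)
  masks <- vector("list", nl)
  for (l in seq_len(nl)) {
    if (ncol(X) != layers[[l]]$in_dim) {
      stop_dims(sprintf("encoder layer %d input", l), ncol(X),
                layers[[l]]$in_dim)
    }
    if (training && dropout > 0) {
      m <- matrix((stats::runif(length(X)) >= dropout) / (1 - dropout),
                  nrow(X), ncol(X))
      masks[[l]] <- m
      X <- X * m
    }
    act <- if (l < nl) "elu" else "identity"
    fw <- lcat_layer_forward(X, layers[[l]], graph, activation = act,
                             return_cache = TRUE)
    caches[[l]] <- fw$cache
    X <- fw$out
  }
  if (!return_cache) return(X)
  list(E = X, caches = caches, masks = masks)
}

# Backward through the full encoder stack; returns per-layer parameter
# gradients (same order as `layers`).
lcat_encode_backward <- function(enc, layers, graph, dE) {
  nl <- length(layers)
  grads <- vector("list", nl)
  d <- dE
  for (l in rev(seq_len(nl))) {
    bk <- lcat_layer_backward(enc$caches[[l]], layers[[l]], graph, d)
    grads[[l]] <- bk[c("gW", "ga", "gl1raw", "gl2raw")]
    d <- bk$dX
    if (!is.null(enc$masks[[l]])) d <- d * enc$masks[[l]]
  }
  grads
}
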