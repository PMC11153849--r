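test_that("pre-convolution obeys its closed forms", {
  set.seed(1)
  g <- random_graph(5, 0.4)
  X <- matrix(rnorm(5 * 3), 5, 3)
  # lambda2 = 0 leaves the features untouched
  expect_identical(convolve_features(X, g, 0), X)
  # lambda2 = 1, single neighbor: (X_i + X_j) / 2
  Y2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  g2 <- graph_neighborhoods(Y2)
  X2 <- rbind(c(2, 0), c(0, 4))
  expect_equal(convolve_features(X2, g2, 1),
               rbind(c(1, 2), c(1, 2)))
  # random graph vs per-node loop oracle
  expect_lt(max(abs(convolve_features(X, g, 0.5) -
                      oracle_convolve(X, g, 0.5))), 1e-12)
})

test_that("attention logits vanish when gated off and match a scalar oracle", {
  set.seed(2)
  g <- random_graph(4, 0.3)
  X <- matrix(rnorm(4 * 3), 4, 3)
  ly <- lcat_layer(3, 2, lambda_mode = "fixed", lambda1 = 0, lambda2 = 0)
  expect_true(all(attention_logits(X, ly, g) == 0))
  ly1 <- lcat_layer(3, 2, lambda_mode = "fixed", lambda1 = 1, lambda2 = 0)
  ly1$a <- rep(0, 4)
  expect_true(all(attention_logits(X, ly1, g) == 0))
  # two-node toy with hand-set parameters
  W <- matrix(c(1, 0, 0, 1), 2, 2)
  a <- c(1, -1, 2, 0.5)
  ly2 <- lcat_layer(2, 2, lambda_mode = "fixed", lambda1 = 1, lambda2 = 0)
  ly2$W <- W; ly2$a <- a
  X3 <- rbind(c(1, 2), c(-1, 0.5))
  g3 <- graph_neighborhoods(matrix(1, 2, 2))
  got <- attention_logits(X3, ly2, g3)
  manual <- function(i, j) {
    u <- sum(a * c(X3[i, ] %*% W, X3[j, ] %*% W))
    if (u > 0) u else 0.2 * u
  }
  for (i in 1:2) for (j in 1:2) expect_equal(got[i, j], manual(i, j))
})

test_that("attention normalization is a masked softmax", {
  g <- graph_neighborhoods(matrix(1, 4, 4))  # fully connected, |N| = 4
  rho <- normalize_attention(matrix(0, 4, 4), g)
  expect_equal(unname(rho), matrix(0.25, 4, 4))
  # logits {0, ln 3} over a 2-neighbor set
  Y <- diag(2); Y[1, 2] <- Y[2, 1] <- 1
  g2 <- graph_neighborhoods(Y)
  lg <- matrix(0, 2, 2); lg[1, 2] <- log(3)
  rho2 <- normalize_attention(lg, g2)
  expect_equal(rho2[1, ], c(0.25, 0.75), ignore_attr = TRUE)
  # isolated node (self-loop only) gets weight 1 on itself
  Y3 <- diag(3); Y3[1, 2] <- Y3[2, 1] <- 1
  rho3 <- normalize_attention(matrix(rnorm(9), 3, 3),
                              graph_neighborhoods(Y3))
  expect_equal(rho3[3, 3], 1)
  expect_equal(rowSums(rho3), rep(1, 3), ignore_attr = TRUE)
})

test_that("layer limits reproduce the three classical behaviours", {
  set.seed(3)
  for (rep in 1:20) {
    n <- 10
    g <- random_graph(n, runif(1, 0.3, 0.6))
    X <- matrix(rnorm(n * 6), n, 6)
    W <- matrix(rnorm(6 * 4, sd = 0.5), 6, 4)
    a <- rnorm(8, sd = 0.5)

    # lambda1 = 0: uniform mean aggregation over the closed neighborhood
    ly <- lcat_layer(6, 4, lambda_mode = "fixed", lambda1 = 0, lambda2 = 0)
    ly$W <- W; ly$a <- a
    out <- lcat_layer_forward(X, ly, g, activation = "identity")
    H <- X %*% W
    mean_agg <- t(sapply(seq_len(n), function(i) {
      colMeans(H[g$nbrs[[i]], , drop = FALSE])
    }))
    expect_lt(max(abs(out - mean_agg)), 1e-6)

    # lambda1 = 1, lambda2 = 0: plain graph attention (independent oracle)
    ly$lambda_fixed <- c(1, 0)
    out_gat <- lcat_layer_forward(X, ly, g, activation = "identity")
    expect_lt(max(abs(out_gat - oracle_gat(X, W, a, 0.2, g))), 1e-6)

    # lambda1 = lambda2 = 1: attention computed on convolved features
    ly$lambda_fixed <- c(1, 1)
    out_cat <- lcat_layer_forward(X, ly, g, activation = "identity")
    Xc <- convolve_features(X, g, 1)
    expect_lt(max(abs(out_cat - oracle_gat(Xc, W, a, 0.2, g))), 1e-6)
  }
})

test_that("outputs are continuous in the interpolation scalars", {
  set.seed(4)
  g <- random_graph(8, 0.4)
  X <- matrix(rnorm(8 * 5), 8, 5)
  ly <- lcat_layer(5, 3, lambda_mode = "fixed", lambda1 = 0.5, lambda2 = 0.5)
  base <- lcat_layer_forward(X, ly, g, activation = "identity")
  ly2 <- ly; ly2$lambda_fixed <- c(0.5 + 1e-7, 0.5 - 1e-7)
  nudged <- lcat_layer_forward(X, ly2, g, activation = "identity")
  expect_lt(max(abs(base - nudged)), 1e-4)
})

test_that("stacked encoder equals composing the exported primitives", {
  set.seed(5)
  n <- 10
  g <- random_graph(n, 0.4)
  X <- matrix(rnorm(n * n), n, n)
  layers <- list(lcat_layer(n, 6), lcat_layer(6, 4))
  E <- lcat_encode(X, layers, g)
  # oracle: run each layer through the primitive ops, ELU between layers
  cur <- X
  for (l in 1:2) {
    lam <- layer_lambdas(layers[[l]])
    conv <- convolve_features(cur, g, lam[2])
    rho <- normalize_attention(attention_logits(conv, layers[[l]], g), g)
    Z <- rho %*% (conv %*% layers[[l]]$W)
    cur <- if (l == 1) ifelse(Z > 0, Z, expm1(Z)) else Z
  }
  expect_lt(max(abs(E - cur)), 1e-10)
  # determinism without dropout
  expect_identical(E, lcat_encode(X, layers, g))
})

test_that("attention weights sum to one on every forward pass", {
  set.seed(6)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    g <- random_graph(n, runif(1, 0.2, 0.7))
    ly <- lcat_layer(n, 4)
    fw <- lcat_layer_forward(matrix(rnorm(n * n), n, n), ly, g,
                             return_cache = TRUE)
    expect_equal(rowSums(fw$cache$rho), rep(1, n), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("node permutation permutes embeddings identically", {
  set.seed(7)
  n <- 9
  Y <- matrix(runif(n * n), n, n); Y <- (Y + t(Y)) / 2
  Y[Y < 0.4] <- 0; diag(Y) <- 1
  X <- matrix(rnorm(n * 5), n, 5)
  layers <- list(lcat_layer(5, 4), lcat_layer(4, 3))
  g <- graph_neighborhoods(Y)
  E <- lcat_encode(X, layers, g)
  p <- sample(n)
  gp <- graph_neighborhoods(Y[p, p])
  Ep <- lcat_encode(X[p, , drop = FALSE], layers, gp)
  expect_lt(max(abs(Ep - E[p, , drop = FALSE])), 1e-10)
})

test_that("analytic gradients match finite differences", {
  set.seed(8)
  n <- 7
  Y <- matrix(runif(n * n), n, n); Y <- (Y + t(Y)) / 2
  Y[Y < 0.35] <- 0; diag(Y) <- 1
  g <- graph_neighborhoods(Y)
  layers <- list(lcat_layer(n, 4), lcat_layer(4, 4))
  dec <- mlp_decoder(4)
  idx_d <- c(1, 2, 3); idx_m <- c(5, 6, 7); z <- c(1, 0, 1)
  loss_fn <- function(layers, dec) {
    E <- lcat_encode(Y, layers, g)
    bce_loss(lcatmd:::decoder_forward(E, idx_d, idx_m, dec), z, "mean")
  }
  enc <- lcat_encode(Y, layers, g, return_cache = TRUE)
  fw <- lcatmd:::decoder_forward(enc$E, idx_d, idx_m, dec,
                                 return_cache = TRUE)
  bk <- lcatmd:::decoder_backward(enc$E, fw$cache, dec, fw$s, z,
                                  1 / length(z))
  egr <- lcatmd:::lcat_encode_backward(enc, layers, g, bk$dE)
  h <- 1e-6
  fd <- function(get, set) {
    x0 <- get(); grad <- x0 * 0
    for (i in seq_along(x0)) {
      xp <- x0; xp[i] <- xp[i] + h; set(xp); lp <- loss_fn(layers, dec)
      xm <- x0; xm[i] <- xm[i] - h; set(xm); lm <- loss_fn(layers, dec)
      grad[i] <- (lp - lm) / (2 * h); set(x0)
    }
    grad
  }
  expect_lt(max(abs(fd(function() layers[[1]]$W,
                       function(x) layers[[1]]$W <<- x) - egr[[1]]$gW)),
            1e-5)
  expect_lt(max(abs(fd(function() layers[[2]]$a,
                       function(x) layers[[2]]$a <<- x) - egr[[2]]$ga)),
            1e-5)
  expect_lt(abs(fd(function() layers[[1]]$lambda1_raw,
                   function(x) layers[[1]]$lambda1_raw <<- x) -
                  egr[[1]]$gl1raw), 1e-5)
  expect_lt(abs(fd(function() layers[[2]]$lambda2_raw,
                   function(x) layers[[2]]$lambda2_raw <<- x) -
                  egr[[2]]$gl2raw), 1e-5)
  expect_lt(max(abs(fd(function() dec$W1,
                       function(x) dec$W1 <<- x) - bk$gW1)), 1e-5)
})

test_that("permutation symmetry: equal features and uniform attention give equal rows", {
  g <- graph_neighborhoods(matrix(1, 6, 6))
  X <- matrix(1, 6, 3)
  ly <- lcat_layer(3, 2, lambda_mode = "fixed", lambda1 = 0, lambda2 = 0.5)
  out <- lcat_layer_forward(X, ly, g, activation = "identity")
  expect_lt(max(abs(sweep(out, 2, out[1, ]))), 1e-12)
})
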