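#' Training configuration
#'
#' Collects the tunable parameters of [mdassoc()]. Defaults reproduce the
#' published operating point of the method: learning rate 0.0005 and
#' embedding width 256, with a 2-layer encoder, 10 hardness buckets, and
#' input dropout 0.1.
#'
#' @param learning_rate Adam step size, default 0.0005.
#' @param embedding_dim output embedding width `F`, default 256.
#' @param hidden_dim width of intermediate encoder layers; defaults to
#'   `embedding_dim`.
#' @param epochs number of training epochs `n` (also the horizon of the
#'   self-paced schedule), default 200.
#' @param n_layers number of encoder layers, default 2.
#' @param bucket_count hardness bucket count `k`, default 10.
#' @param dropout input dropout rate during training, default 0.1.
#' @param leaky_slope LeakyReLU negative slope in the attention score,
#'   default 0.2.
#' @param edge_threshold network entries above this value become graph
#'   edges; default 0 (all nonzero entries).
#' @param sampler `"spe"` (self-paced iterative resampling, the default) or
#'   `"random"` (uniform re-draw each epoch, the ablation baseline).
#' @param lambda_mode `"free"` (both interpolation scalars trainable) or a
#'   frozen ablation corner `"gcn"`, `"gat"`, `"cat"`.
#' @param resample_every re-draw the negative set every this many epochs,
#'   default 1.
#' @param raw_bandwidth GIP raw bandwidth, default 1.
#' @param optim_reduction loss reduction driving the optimizer, `"mean"`
#'   (default, step size independent of batch size) or `"sum"`; the
#'   reported log loss is always the sum.
#' @param eps score clipping constant in the loss, default `1e-7`.
#' @param verbose print a progress line every 50 epochs.
#' @return A list of class `"mdassoc_control"`.
#' @export
mdassoc_control <- function(learning_rate = 5e-4, embedding_dim = 256,
                            hidden_dim = NULL, epochs = 200, n_layers = 2,
                            bucket_count = 10, dropout = 0.1,
                            leaky_slope = 0.2, edge_threshold = 0,
                            sampler = c("spe", "random"),
                            lambda_mode = c("free", "gcn", "gat", "cat"),
                            resample_every = 1, raw_bandwidth = 1,
                            optim_reduction = c("mean", "sum"),
                            eps = 1e-7, verbose = FALSE) {
  sampler <- match.arg(sampler)
  lambda_mode <- match.arg(lambda_mode)
  optim_reduction <- match.arg(optim_reduction)
  stopifnot(learning_rate > 0, embedding_dim >= 1, epochs >= 0,
            n_layers >= 1, bucket_count >= 1, dropout >= 0, dropout < 1,
            resample_every >= 1)
  structure(list(learning_rate = learning_rate,
                 embedding_dim = embedding_dim,
                 hidden_dim = hidden_dim %||% embedding_dim,
                 epochs = epochs, n_layers = n_layers,
                 bucket_count = bucket_count, dropout = dropout,
                 leaky_slope = leaky_slope, edge_threshold = edge_threshold,
                 sampler = sampler, lambda_mode = lambda_mode,
                 resample_every = resample_every,
                 raw_bandwidth = raw_bandwidth,
                 optim_reduction = optim_reduction, eps = eps,
                 verbose = verbose),
            class = "mdassoc_control")
}

# One Adam update; state carries first/second moments, t is the shared step.
adam_update <- function(x, g, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mhat <- st$m / (1 - b1^t)
  vhat <- st$v / (1 - b2^t)
  list(x = x - lr * mhat / (sqrt(vhat) + eps), st = st)
}

adam_state <- function(x) list(m = x * 0, v = x * 0)

#' Fit the microbe-drug association model
#'
#' End-to-end training of the predictor on a training association table.
#' The pipeline: (1) drug and microbe GIP similarities are computed from
#' the training adjacency and integrated entrywise with the optional
#' secondary similarities; (2) the block heterogeneous network `Y` is
#' assembled once (similarities do not depend on model parameters) and its
#' rows become the initial node features; (3) each epoch, the learnable
#' convolutional-attention encoder embeds all nodes, the MLP decoder scores
#' the current balanced sample set (all training positives plus the current
#' negative draw), one Adam step is taken on the binary cross-entropy, and
#' every candidate negative is re-scored; (4) the first epoch's negatives
#' are a uniform undersample, later epochs re-draw them with the self-paced
#' hardness-bucket sampler (or uniformly, under the `"random"` ablation).
#'
#' @param assoc training [association_table()] (at least one positive).
#' @param drug_sim,microbe_sim optional precomputed secondary similarity
#'   matrices, integrated entrywise with the GIP similarities.
#' @param control an [mdassoc_control()].
#' @param seed optional integer seed; identical seed + config gives a
#'   bit-identical fit.
#' @param similarity optional list with elements `drug` and `microbe`
#'   holding ready-made integrated similarity matrices; when supplied, GIP
#'   computation and secondary integration are skipped (used for
#'   leakage-mode comparisons in cross-validation).
#' @param excluded_pairs optional two-column matrix of (drug, microbe)
#'   index pairs removed from the candidate negative pool.
#'
#' @return An object of class `"mdassoc"`: list with `scores` (the
#'   `Nd x Nm` predicted score matrix), `layers`, `decoder`, `log`
#'   (per-epoch data frame: `epoch`, `loss` (sum-reduced), `beta`, `n_neg`,
#'   `neg_mean_hardness`), `lambdas` (per-layer interpolation coefficients),
#'   `assoc`, `control`, `seed`.
#' @seealso [predict.mdassoc()], [mdassoc_cv()], [rank_candidates()]
#' @export
#' @examples
#' d <- simulate_mda_data(25, 10, latent_rank = 2, target_density = 0.1, seed = 1)
#' fit <- mdassoc(d$assoc, d$drug_sim, d$microbe_sim,
#'                control = mdassoc_control(epochs = 5, embedding_dim = 8),
#'                seed = 1)
#' fit
mdassoc <- function(assoc, drug_sim = NULL, microbe_sim = NULL,
                    control = mdassoc_control(), seed = NULL,
                    similarity = NULL, excluded_pairs = NULL) {
  stopifnot(inherits(assoc, "association_table"),
            inherits(control, "mdassoc_control"))
  A <- assoc$A
  if (sum(A) < 1) stop("training table has no positive pairs", call. = FALSE)
  with_seed(seed, {
    nd <- nrow(A); nm <- ncol(A)
    if (is.null(similarity)) {
      Sd <- integrate_similarity(gip_similarity(A, control$raw_bandwidth),
                                 drug_sim)
      Sm <- integrate_similarity(gip_similarity(t(A), control$raw_bandwidth),
                                 microbe_sim)
    } else {
      Sd <- similarity$drug; Sm <- similarity$microbe
    }
    net <- build_hetnet(assoc, Sd, Sm)
    graph <- graph_neighborhoods(net$Y, control$edge_threshold)
    n <- nd + nm
    dims <- c(n, rep(control$hidden_dim, control$n_layers - 1),
              control$embedding_dim)
    layers <- lapply(seq_len(control$n_layers), function(l) {
      lcat_layer(dims[l], dims[l + 1], control$leaky_slope,
                 control$lambda_mode)
    })
    decoder <- mlp_decoder(control$embedding_dim)

    positives <- which(A == 1, arr.ind = TRUE)
    dimnames(positives) <- NULL
    pool <- which(A == 0, arr.ind = TRUE)
    dimnames(pool) <- NULL
    if (!is.null(excluded_pairs) && nrow(excluded_pairs) > 0) {
      keys <- paste(pool[, 1], pool[, 2])
      drop_keys <- paste(excluded_pairs[, 1], excluded_pairs[, 2])
      pool <- pool[!(keys %in% drop_keys), , drop = FALSE]
    }
    nP <- nrow(positives)

    st <- lapply(layers, function(l) {
      list(W = adam_state(l$W), a = adam_state(l$a),
           l1 = adam_state(0), l2 = adam_state(0))
    })
    st_dec <- list(W1 = adam_state(decoder$W1), W2 = adam_state(decoder$W2))

    log_rows <- vector("list", control$epochs)
    negatives <- NULL
    pool_scores <- NULL
    tstep <- 0

    for (i in seq_len(control$epochs) - 1L) {
      beta_i <- NA_real_
      if (i == 0L) {
        negatives <- initial_random_undersample(pool, nP)
      } else if (control$sampler == "spe") {
        if (i %% control$resample_every == 0L) {
          negatives <- spe_sample_iteration(pool, pool_scores,
                                            control$bucket_count, i,
                                            control$epochs, nP)
          beta_i <- attr(negatives, "diagnostics")$beta
        }
      } else {
        negatives <- initial_random_undersample(pool, nP)
      }
      idx_d <- c(positives[, 1], negatives[, 1])
      idx_m <- nd + c(positives[, 2], negatives[, 2])
      z <- c(rep(1, nP), rep(0, nrow(negatives)))

      enc <- lcat_encode(net$Y, layers, graph, dropout = control$dropout,
                         training = TRUE, return_cache = TRUE)
      fw <- decoder_forward(enc$E, idx_d, idx_m, decoder,
                            return_cache = TRUE)
      loss_sum <- bce_loss(fw$s, z, "sum", control$eps)
      if (!is.finite(loss_sum)) {
        stop(sprintf("non-finite loss at epoch %d (loss = %s); aborting",
                     i, format(loss_sum)), call. = FALSE)
      }
      scale <- if (control$optim_reduction == "mean") 1 / length(z) else 1
      bk <- decoder_backward(enc$E, fw$cache, decoder, fw$s, z, scale)
      egr <- lcat_encode_backward(enc, layers, graph, bk$dE)

      tstep <- tstep + 1
      lr <- control$learning_rate
      up <- adam_update(decoder$W1, bk$gW1, st_dec$W1, lr, tstep)
      decoder$W1 <- up$x; st_dec$W1 <- up$st
      up <- adam_update(decoder$W2, bk$gW2, st_dec$W2, lr, tstep)
      decoder$W2 <- up$x; st_dec$W2 <- up$st
      for (l in seq_along(layers)) {
        up <- adam_update(layers[[l]]$W, egr[[l]]$gW, st[[l]]$W, lr, tstep)
        layers[[l]]$W <- up$x; st[[l]]$W <- up$st
        up <- adam_update(layers[[l]]$a, egr[[l]]$ga, st[[l]]$a, lr, tstep)
        layers[[l]]$a <- up$x; st[[l]]$a <- up$st
        if (layers[[l]]$train_l1) {
          up <- adam_update(layers[[l]]$lambda1_raw, egr[[l]]$gl1raw,
                            st[[l]]$l1, lr, tstep)
          layers[[l]]$lambda1_raw <- up$x; st[[l]]$l1 <- up$st
        }
        if (layers[[l]]$train_l2) {
          up <- adam_update(layers[[l]]$lambda2_raw, egr[[l]]$gl2raw,
                            st[[l]]$l2, lr, tstep)
          layers[[l]]$lambda2_raw <- up$x; st[[l]]$l2 <- up$st
        }
      }

      E_eval <- lcat_encode(net$Y, layers, graph, training = FALSE)
      pool_scores <- decoder_forward(E_eval, pool[, 1], nd + pool[, 2],
                                     decoder)
      neg_scores <- decoder_forward(E_eval, negatives[, 1],
                                    nd + negatives[, 2], decoder)
      log_rows[[i + 1L]] <- data.frame(
        epoch = i, loss = loss_sum, beta = beta_i,
        n_neg = nrow(negatives),
        neg_mean_hardness = mean(spe_hardness(neg_scores, 0)))
      if (control$verbose && i %% 50 == 0) {
        message(sprintf("epoch %4d  loss %.4f", i, loss_sum))
      }
    }

    E_final <- lcat_encode(net$Y, layers, graph, training = FALSE)
    scores <- score_all_pairs(E_final, nd, nm, decoder)
    dimnames(scores) <- list(assoc$drug_ids, assoc$microbe_ids)
    lambdas <- t(vapply(layers, layer_lambdas, numeric(2)))
    structure(list(scores = scores, layers = layers, decoder = decoder,
                   log = if (control$epochs > 0) do.call(rbind, log_rows)
                         else data.frame(),
                   lambdas = lambdas, assoc = assoc, control = control,
                   seed = seed, nd = nd, nm = nm,
                   call = match.call()),
              class = "mdassoc")
  })
}
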