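#' Gaussian interaction-profile kernel bandwidth
#'
#' Normalized kernel bandwidth for the GIP similarity: the raw bandwidth
#' divided by the mean squared Euclidean norm of the interaction profiles,
#' `mu = raw_bandwidth / mean(||profile_i||^2)`.
#'
#' @param profiles matrix whose rows are binary interaction profiles (for
#'   microbes the columns of the association matrix `A`; for drugs its rows).
#' @param raw_bandwidth positive scalar, conventionally 1.
#' @return The scalar bandwidth `mu`.
#' @export
#' @examples
#' gip_bandwidth(rbind(c(1, 0), c(0, 1)))  # 1
gip_bandwidth <- function(profiles, raw_bandwidth = 1) {
  profiles <- as.matrix(profiles)
  stopifnot(raw_bandwidth > 0)
  msq <- mean(rowSums(profiles^2))
  if (msq == 0) {
    stop("all interaction profiles are all-zero; GIP bandwidth undefined ",
         "(cold-start dataset must be handled by the caller)", call. = FALSE)
  }
  raw_bandwidth / msq
}

#' Gaussian interaction-profile kernel similarity
#'
#' `S[i, j] = exp(-mu * ||profile_i - profile_j||^2)` with `mu` from
#' [gip_bandwidth()]. The result is symmetric with exact unit diagonal and
#' entries in (0, 1].
#'
#' @inheritParams gip_bandwidth
#' @return Square numeric similarity matrix (N x N for N profiles), dimnames
#'   taken from the profile rownames.
#' @export
#' @examples
#' A <- matrix(c(1, 0, 0, 1), 2, 2)
#' gip_similarity(A)        # drug similarity (rows of A)
#' gip_similarity(t(A))     # microbe similarity (columns of A)
gip_similarity <- function(profiles, raw_bandwidth = 1) {
  profiles <- as.matrix(profiles)
  mu <- gip_bandwidth(profiles, raw_bandwidth)
  n2 <- rowSums(profiles^2)
  d2 <- outer(n2, n2, "+") - 2 * tcrossprod(profiles)
  d2 <- pmax(d2, 0)                       # guard tiny negative round-off
  S <- exp(-mu * d2)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(rownames(profiles), rownames(profiles))
  S
}

#' Integrate GIP similarity with a secondary similarity
#'
#' Entrywise average where the secondary similarity is informative:
#' `result[i, j] = (gip[i, j] + secondary[i, j]) / 2` wherever
#' `secondary[i, j] != 0`, and `gip[i, j]` otherwise. An absent secondary
#' matrix (`NULL`) is equivalent to all zeros, i.e. the GIP matrix is
#' returned unchanged. The branch is applied per entry: a single measured
#' pair does not change the integration of unmeasured pairs.
#'
#' @param gip square GIP similarity matrix.
#' @param secondary optional square matrix of the same shape (precomputed
#'   drug structural or microbe functional similarity), or `NULL`.
#' @return Integrated similarity matrix, same shape as `gip`.
#' @export
integrate_similarity <- function(gip, secondary = NULL) {
  gip <- as.matrix(gip)
  if (is.null(secondary)) return(gip)
  secondary <- as.matrix(secondary)
  if (!all(dim(gip) == dim(secondary))) {
    stop_dims("integrate_similarity", dim(secondary), dim(gip))
  }
  out <- gip
  has <- secondary != 0
  out[has] <- (gip[has] + secondary[has]) / 2
  out
}

#' Assemble the heterogeneous drug-microbe network
#'
#' Builds the `(Nd+Nm) x (Nd+Nm)` block matrix placing the integrated drug
#' similarity, the association matrix `A` and its transpose, and the
#' integrated microbe similarity:
#' `Y = rbind(cbind(S_drug, A), cbind(t(A), S_microbe))`. Rows of `Y` double
#' as the initial node features for the encoder (drugs first, then microbes).
#'
#' @param assoc an [association_table()].
#' @param drug_sim `Nd x Nd` similarity matrix.
#' @param microbe_sim `Nm x Nm` similarity matrix.
#' @return An object of class `"hetnet"`: list with `Y`, `nd`, `nm`,
#'   `drug_ids`, `microbe_ids`.
#' @export
build_hetnet <- function(assoc, drug_sim, microbe_sim) {
  stopifnot(inherits(assoc, "association_table"))
  A <- assoc$A
  nd <- nrow(A); nm <- ncol(A)
  drug_sim <- as.matrix(drug_sim); microbe_sim <- as.matrix(microbe_sim)
  if (!all(dim(drug_sim) == c(nd, nd))) {
    stop_dims("drug similarity", dim(drug_sim), c(nd, nd))
  }
  if (!all(dim(microbe_sim) == c(nm, nm))) {
    stop_dims("microbe similarity", dim(microbe_sim), c(nm, nm))
  }
  Y <- rbind(cbind(drug_sim, A), cbind(t(A), microbe_sim))
  ids <- c(assoc$drug_ids, assoc$microbe_ids)
  dimnames(Y) <- list(ids, ids)
  structure(list(Y = Y, nd = nd, nm = nm,
                 drug_ids = assoc$drug_ids, microbe_ids = assoc$microbe_ids),
            class = "hetnet")
}

#' Extract the four blocks of a heterogeneous network
#'
#' Inverse of [build_hetnet()]: returns the drug-similarity, association,
#' and microbe-similarity blocks.
#'
#' @param net a `"hetnet"` object.
#' @return List with `drug_sim`, `A`, `At`, `microbe_sim`.
#' @export
hetnet_blocks <- function(net) {
  stopifnot(inherits(net, "hetnet"))
  nd <- net$nd; nm <- net$nm
  list(drug_sim    = net$Y[seq_len(nd), seq_len(nd), drop = FALSE],
       A           = net$Y[seq_len(nd), nd + seq_len(nm), drop = FALSE],
       At          = net$Y[nd + seq_len(nm), seq_len(nd), drop = FALSE],
       microbe_sim = net$Y[nd + seq_len(nm), nd + seq_len(nm), drop = FALSE])
}

#' @export
print.hetnet <- function(x, ...) {
  cat(sprintf("Heterogeneous network: %d drugs + %d microbes = %d nodes\n",
              x$nd, x$nm, x$nd + x$nm))
  invisible(x)
}

# Convenience: GIP + integration + block assembly from a training table.
# Secondary similarities are optional precomputed matrices.
#' Build the network directly from an association table
#'
#' Computes drug and microbe GIP similarities from `assoc`, integrates the
#' optional secondary similarities entrywise, and assembles the block
#' network. This is the network construction used by [mdassoc()].
#'
#' @inheritParams build_hetnet
#' @param drug_secondary,microbe_secondary optional precomputed similarity
#'   matrices (e.g. chemical-structure or protein-network functional
#'   similarities), or `NULL`.
#' @param raw_bandwidth GIP raw bandwidth, default 1.
#' @return A `"hetnet"` object.
#' @export
mda_network <- function(assoc, drug_secondary = NULL, microbe_secondary = NULL,
                        raw_bandwidth = 1) {
  Sd <- integrate_similarity(gip_similarity(assoc$A, raw_bandwidth),
                             drug_secondary)
  Sm <- integrate_similarity(gip_similarity(t(assoc$A), raw_bandwidth),
                             microbe_secondary)
  build_hetnet(assoc, Sd, Sm)
}
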