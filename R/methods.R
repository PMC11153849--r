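# S3 methods for fitted "mdassoc" objects.

#' @export
print.mdassoc <- function(x, ...) {
  cat("Microbe-drug association model (graph convolutional attention + MLP)\n")
  cat(sprintf("  %d drugs x %d microbes, %d known associations\n",
              x$nd, x$nm, sum(x$assoc$A)))
  cat(sprintf("  encoder: %d layer(s), embedding width %d, lambda mode '%s'\n",
              length(x$layers), x$control$embedding_dim,
              x$control$lambda_mode))
  cat(sprintf("  sampler: %s, %d epochs", x$control$sampler,
              x$control$epochs))
  if (nrow(x$log) > 0) {
    cat(sprintf(", final loss (sum) %.4f", x$log$loss[nrow(x$log)]))
  }
  cat("\n  interpolation coefficients per layer:\n")
  for (l in seq_len(nrow(x$lambdas))) {
    cat(sprintf("    layer %d: lambda1 = %.3f, lambda2 = %.3f\n",
                l, x$lambdas[l, 1], x$lambdas[l, 2]))
  }
  invisible(x)
}

#' @export
summary.mdassoc <- function(object, ...) {
  pos <- object$scores[object$assoc$A == 1]
  neg <- object$scores[object$assoc$A == 0]
  out <- list(fit = object,
              score_summary = rbind(positives = summary(pos),
                                    candidates = summary(neg)),
              separation = mean(pos) - mean(neg))
  class(out) <- "summary.mdassoc"
  out
}

#' @export
print.summary.mdassoc <- function(x, ...) {
  print(x$fit)
  cat("\nScore distribution (training positives vs candidate pairs):\n")
  print(round(x$score_summary, 4))
  cat(sprintf("\nMean score separation (positives - candidates): %.4f\n",
              x$separation))
  invisible(x)
}

#' Interpolation coefficients of a fitted model
#'
#' The model's "coefficients" in the usual sense are the two interpolation
#' scalars per encoder layer: `lambda1` (attention strength) and `lambda2`
#' (pre-convolution strength).
#'
#' @param object an `"mdassoc"` fit.
#' @param ... unused.
#' @return Matrix with one row per layer, columns `lambda1`, `lambda2`.
#' @export
coef.mdassoc <- function(object, ...) {
  out <- object$lambdas
  dimnames(out) <- list(paste0("layer", seq_len(nrow(out))),
                        c("lambda1", "lambda2"))
  out
}

#' Predicted association scores
#'
#' @param object an `"mdassoc"` fit.
#' @param drugs,microbes optional identifier vectors selecting a submatrix
#'   of the score matrix.
#' @param pairs optional two-column matrix of (drug, microbe) indices or
#'   identifiers; returns a vector of scores for those pairs.
#' @param ... unused.
#' @return Score matrix (or vector for `pairs`), entries in (0, 1).
#' @export
predict.mdassoc <- function(object, drugs = NULL, microbes = NULL,
                            pairs = NULL, ...) {
  if (!is.null(pairs)) return(object$scores[as.matrix(pairs)])
  s <- object$scores
  if (!is.null(drugs)) s <- s[drugs, , drop = FALSE]
  if (!is.null(microbes)) s <- s[, microbes, drop = FALSE]
  s
}

#' @export
fitted.mdassoc <- function(object, ...) object$scores

#' Raw residuals of the fitted score matrix
#'
#' `A - Score`: negative values on candidate pairs the model scores highly
#' (the predicted novel associations), values near 0 on well-fit entries.
#'
#' @inheritParams coef.mdassoc
#' @return `Nd x Nm` numeric matrix.
#' @export
residuals.mdassoc <- function(object, ...) object$assoc$A - object$scores

#' Simulate adjacency matrices from the fitted scores
#'
#' Draws binary association matrices with independent Bernoulli entries at
#' the fitted score probabilities.
#'
#' @param object an `"mdassoc"` fit.
#' @param nsim number of matrices, default 1.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return List of `nsim` binary matrices.
#' @export
simulate.mdassoc <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      matrix(stats::rbinom(length(object$scores), 1, object$scores),
             object$nd, object$nm, dimnames = dimnames(object$scores))
    })
  })
}

#' Training diagnostics plot
#'
#' Two base-graphics panels: the per-epoch training loss, and the mean
#' hardness of the sampled negative set together with the self-paced factor
#' schedule.
#'
#' @param x an `"mdassoc"` fit with at least one training epoch.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mdassoc <- function(x, ...) {
  if (nrow(x$log) == 0) {
    stop("nothing to plot: model was fitted with epochs = 0", call. = FALSE)
  }
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$log$epoch, x$log$loss, type = "l", xlab = "epoch",
                 ylab = "loss (sum BCE)", main = "Training loss", ...)
  graphics::plot(x$log$epoch, x$log$neg_mean_hardness, type = "l",
                 xlab = "epoch", ylab = "mean hardness of drawn negatives",
                 main = "Self-paced sampling", ...)
  ok <- is.finite(x$log$beta)
  if (any(ok)) {
    graphics::lines(x$log$epoch[ok],
                    x$log$beta[ok] / max(x$log$beta[ok]) *
                      max(x$log$neg_mean_hardness, na.rm = TRUE),
                    lty = 2, col = "grey50")
    graphics::legend("topleft", lty = c(1, 2), col = c("black", "grey50"),
                     legend = c("hardness", "beta (rescaled)"), bty = "n")
  }
  invisible(x)
}
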