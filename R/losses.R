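#' Decoupled contrastive learning (DCL) loss
#'
#' For each anchor projection the positive term is the weighted cosine
#' similarity to its paired view divided by the temperature, and the
#' negative term is the log-sum-exp of similarities to both views of
#' every other sample in the batch (the positive pair is excluded from
#' the denominator, which is what decouples the two terms). The loss is
#' averaged over all 2N anchors (both views of every sample).
#'
#' @param Z1,Z2 N x d matrices of unit-norm projections; row i of
#'   \code{Z1} and row i of \code{Z2} are the two views of sample i.
#' @param weights length-N positive-pair weights in (0, 1]; the
#'   orthology-sourced pairs use a reduced weight (0.8 by default
#'   elsewhere), all other sources weight 1.
#' @param temperature softmax temperature, default 0.1.
#' @return scalar loss value.
#' @export
dclLoss <- function(Z1, Z2, weights = rep(1, nrow(Z1)), temperature = 0.1) {
  dclLossGrad(Z1, Z2, weights, temperature, wantGrad = FALSE)$loss
}

#' DCL loss with analytic gradient
#'
#' Same value as \code{\link{dclLoss}}, plus the gradients with respect
#' to the two projection matrices (used by the pre-training loop).
#'
#' @inheritParams dclLoss
#' @param wantGrad compute gradients?
#' @return list with \code{loss} and, if requested, \code{dZ1},
#'   \code{dZ2}.
#' @export
dclLossGrad <- function(Z1, Z2, weights = rep(1, nrow(Z1)),
                        temperature = 0.1, wantGrad = TRUE) {
  N <- nrow(Z1)
  if (N < 2L) stop("DCL loss needs at least 2 samples (no negatives otherwise)")
  if (temperature <= 0) stop("temperature must be positive")
  nz <- c(rowSums(Z1^2), rowSums(Z2^2))
  if (any(abs(nz - 1) > 1e-4)) stop("projection rows must be unit-norm")
  if (length(weights) != N || any(weights <= 0) || any(weights > 1))
    stop("weights must be length N in (0, 1]")
  S <- rbind(Z1, Z2)                    # 2N anchors
  M <- (S %*% t(S)) / temperature
  # exclude both views of the anchor's own sample from the negatives
  sample_of <- rep(seq_len(N), 2L)
  excl <- outer(sample_of, sample_of, "==")
  Mmax <- apply(M + ifelse(excl, -Inf, 0), 1L, max)
  W <- exp(M - Mmax)
  W[excl] <- 0
  R <- rowSums(W)
  lse <- log(R) + Mmax
  pos <- rowSums(Z1 * Z2) / temperature
  # each pair's positive term appears once per view: 2 w_i pos_i over 2N
  loss <- mean(lse) - mean(weights * pos)
  if (!wantGrad) return(list(loss = loss))
  P <- W / R
  dS <- (P %*% S + t(P) %*% S) / (2 * N * temperature)
  dZ1 <- dS[seq_len(N), , drop = FALSE] -
    (weights / (N * temperature)) * Z2
  dZ2 <- dS[N + seq_len(N), , drop = FALSE] -
    (weights / (N * temperature)) * Z1
  list(loss = loss, dZ1 = dZ1, dZ2 = dZ2)
}

#' Masked language modelling loss
#'
#' Cross-entropy between the true one-hot nucleotide identities and the
#' predicted per-position probability vectors, restricted to the masked
#' positions. Probabilities are floored at 1e-12 before the log (a
#' degenerate zero probability at a true base is flagged via the
#' \code{"clamped"} attribute rather than returning -Inf).
#'
#' @param targets L x 4 one-hot matrix of true nucleotides (A, C, G, T).
#' @param probs L x 4 matrix of predicted probabilities (rows sum to 1).
#' @param maskedPositions integer vector of 1-based masked row indices.
#' @return scalar loss, with attribute \code{clamped} (logical).
#' @export
mlmLoss <- function(targets, probs, maskedPositions) {
  if (length(maskedPositions) < 1L) stop("the masked set must be non-empty")
  rs <- rowSums(probs[maskedPositions, , drop = FALSE])
  if (any(abs(rs - 1) > 1e-6)) stop("prediction rows must sum to 1")
  Tm <- targets[maskedPositions, , drop = FALSE]
  Pm <- probs[maskedPositions, , drop = FALSE]
  hit <- rowSums(Tm * Pm)
  present <- rowSums(Tm) > 0
  clamped <- any(present & hit < 1e-12)
  val <- -sum(log(pmax(hit[present], 1e-12))) / length(maskedPositions)
  attr(val, "clamped") <- clamped
  val
}

# Shared masking core: choose floor(fraction * n_valid) distinct valid
# positions and zero their nucleotide tracks; structural tracks are
# kept (masking removes one-hot identity only).
.maskPositions <- function(enc, fraction, seed) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  m <- trackMatrix(enc)
  valid <- which(validMask(enc))
  k <- floor(fraction * length(valid))
  pos <- if (k > 0L)
    withr::with_seed(seed, sort(sample(valid, k))) else integer()
  m[pos, 1:4] <- 0
  list(enc = new("SixTrackEncoding", mat = m, mask = validMask(enc)),
       positions = pos)
}

#' Corrupt an encoding for masked language modelling
#'
#' Draws \code{floor(fraction * L)} valid positions uniformly without
#' replacement and replaces their one-hot nucleotide vectors with zero
#' vectors, producing the corrupted input; splice-junction and
#' codon-start tracks are untouched. The input object is not modified.
#'
#' @param enc a \linkS4class{SixTrackEncoding}.
#' @param fraction fraction of positions to mask (default 0.15, the MLM
#'   masking rate).
#' @param seed RNG seed; the mask is deterministic given the seed.
#' @return list with \code{corrupted} (\linkS4class{SixTrackEncoding})
#'   and \code{maskedPositions} (1-based integer indices).
#' @export
applyMlmCorruption <- function(enc, fraction = 0.15, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  r <- .maskPositions(enc, fraction, seed)
  list(corrupted = r$enc, maskedPositions = r$positions)
}

#' Combine contrastive and MLM losses
#'
#' \code{l_total = (1 - alpha) * l_cl + alpha * l_mlm}. The default
#' alpha of 0.95 puts a higher weight on the MLM term, compensating for
#' the different numerical scales of the two objectives.
#'
#' @param lcl,lmlm component loss values.
#' @param alpha mixing coefficient in [0, 1].
#' @return a \code{loss_report} list with \code{l_cl}, \code{l_mlm},
#'   \code{l_total}, \code{alpha}.
#' @export
combinedLoss <- function(lcl, lmlm, alpha = 0.95) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  out <- list(l_cl = as.numeric(lcl), l_mlm = as.numeric(lmlm),
              l_total = (1 - alpha) * as.numeric(lcl) +
                alpha * as.numeric(lmlm),
              alpha = alpha)
  class(out) <- "loss_report"
  out
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("loss: total %.4f = (1 - %.2f) * CL %.4f + %.2f * MLM %.4f\n",
              x$l_total, x$alpha, x$l_cl, x$alpha, x$l_mlm))
  invisible(x)
}
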