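#' Selective state-space encoder configuration
#'
#' @param dModel hidden width per position.
#' @param dState state dimension N of the per-channel SSM.
#' @param nLayers number of stacked SSM blocks.
#' @param maxLen maximum sequence length accepted by \code{encodeSequence}.
#' @param inputTracks 6 (full six-track encoding) or 4 (nucleotides only).
#' @param projDim projection-head output width.
#' @param pooling \code{"mean"} (masked mean over positions, default) or
#'   \code{"max"}.
#' @param selective if \code{FALSE}, B, C and the step size are learned
#'   constants rather than functions of the input (the non-selective,
#'   LTI ablation variant; parameter tensors are kept so the two
#'   variants are parameter-matched).
#' @return a validated list of class \code{ssm_config}.
#' @export
ssmConfig <- function(dModel = 64L, dState = 8L, nLayers = 2L,
                      maxLen = 12288L, inputTracks = 6L, projDim = 128L,
                      pooling = c("mean", "max"), selective = TRUE) {
  pooling <- match.arg(pooling)
  cfg <- list(dModel = as.integer(dModel), dState = as.integer(dState),
              nLayers = as.integer(nLayers), maxLen = as.integer(maxLen),
              inputTracks = as.integer(inputTracks),
              projDim = as.integer(projDim), pooling = pooling,
              selective = isTRUE(selective))
  if (any(unlist(cfg[1:6]) <= 0L)) stop("all config dimensions must be positive")
  if (!cfg$inputTracks %in% c(4L, 6L)) stop("inputTracks must be 4 or 6")
  class(cfg) <- "ssm_config"
  cfg
}

.rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
.softplus <- function(x) {
  out <- x
  i <- x <= 30
  out[i] <- log1p(exp(x[i]))
  out
}
.softplusInv <- function(y) {
  out <- y
  i <- y <= 30
  out[i] <- log(expm1(y[i]))
  out
}
.sigmoid <- function(x) 1 / (1 + exp(-x))

# One SSM block's parameters. Step sizes are initialized log-uniform in
# [1e-3, 0.1] (through the softplus bias) and A is the standard
# negative-real diagonal init A[c, j] = -j.
.initLayer <- function(d, n, nLayers, selective) {
  dt0 <- exp(stats::runif(d, log(1e-3), log(0.1)))
  list(
    W_dt = .rmat(d, d, 1 / sqrt(d)) * selective,
    b_dt = .softplusInv(dt0),
    W_B = .rmat(d, n, 1 / sqrt(d)) * selective,
    b_B = if (selective) rep(0, n) else stats::rnorm(n, sd = 1),
    W_C = .rmat(d, n, 1 / sqrt(d)) * selective,
    b_C = if (selective) rep(0, n) else stats::rnorm(n, sd = 1 / sqrt(n)),
    A_log = matrix(rep(log(seq_len(n)), each = d), d, n),
    W_g = .rmat(d, d, 1 / sqrt(d)), b_g = rep(0, d),
    W_o = .rmat(d, d, 1 / sqrt(d * 2 * nLayers)), b_o = rep(0, d)
  )
}

.initSSMParams <- function(cfg, seed = 1L) {
  withr::with_seed(seed, {
    d <- cfg$dModel; n <- cfg$dState
    list(
      W_in = .rmat(cfg$inputTracks, d, 1 / sqrt(cfg$inputTracks)),
      b_in = rep(0, d),
      layers = lapply(seq_len(cfg$nLayers), function(l)
        .initLayer(d, n, cfg$nLayers, cfg$selective)),
      W_p1 = .rmat(d, d, 1 / sqrt(d)), b_p1 = rep(0, d),
      W_p2 = .rmat(d, cfg$projDim, 1 / sqrt(d)), b_p2 = rep(0, cfg$projDim),
      W_mlm = .rmat(d, 4L, 1 / sqrt(d)), b_mlm = rep(0, 4L),
      selectiveFlag = cfg$selective
    )
  })
}

#' Sequence encoder producing fixed-length RNA embeddings
#'
#' Container for an encoder of any supported kind: the selective
#' state-space model (the main architecture), its non-selective LTI
#' ablation, and the two convolutional baselines (a dilated CNN and a
#' CNN-RNN hybrid). All kinds share the \code{\link{encodeSequence}}
#' contract: per-position hidden states plus a pooled, fixed-length
#' embedding, so losses and probes are encoder-agnostic.
#'
#' @slot kind one of \code{"selective"}, \code{"nonselective"},
#'   \code{"dilated_cnn"}, \code{"cnn_rnn"}.
#' @slot config the \code{ssm_config} list.
#' @slot params named list of weight matrices.
#' @export
setClass("RNAEncoder",
  representation(kind = "character", config = "list", params = "list"))

setMethod("show", "RNAEncoder", function(object) {
  cat(sprintf("RNAEncoder (%s): d_model %d, d_state %d, %d layer(s), %s parameters\n",
              object@kind, object@config$dModel, object@config$dState,
              object@config$nLayers,
              format(parameterCount(object), big.mark = ",")))
})

#' Build a sequence encoder
#'
#' @param kind architecture; \code{"selective"} is the state-space
#'   encoder, \code{"nonselective"} its input-independent ablation,
#'   \code{"dilated_cnn"} and \code{"cnn_rnn"} the supervised-baseline
#'   architectures (feature extractors with the same embedding contract).
#' @param config an \code{\link{ssmConfig}}.
#' @param seed RNG seed for weight initialization.
#' @return an \linkS4class{RNAEncoder}.
#' @export
buildEncoder <- function(kind = c("selective", "nonselective",
                                  "dilated_cnn", "cnn_rnn"),
                         config = ssmConfig(), seed = 1L) {
  kind <- match.arg(kind)
  cfg <- config
  if (kind == "nonselective") cfg$selective <- FALSE
  if (kind == "selective") cfg$selective <- TRUE
  params <- switch(kind,
    selective = , nonselective = .initSSMParams(cfg, seed),
    dilated_cnn = .initDilatedCNN(cfg, seed),
    cnn_rnn = .initCNNRNN(cfg, seed))
  new("RNAEncoder", kind = kind, config = unclass(cfg), params = params)
}

#' Encoder presets
#'
#' \code{"micro"} is the desk-scale preset used throughout the test
#' corpus work (2 layers, width 64). \code{"small"} and \code{"base"}
#' target roughly 1.3 and 10.1 million trainable parameters; the exact
#' width is found by a grid search over widths at build time.
#'
#' @param preset one of \code{"micro"}, \code{"small"}, \code{"base"}.
#' @param ... overrides passed to \code{\link{ssmConfig}}.
#' @return an \code{ssm_config}.
#' @export
presetConfig <- function(preset = c("micro", "small", "base"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    micro = list(dModel = 64L, dState = 8L, nLayers = 2L, maxLen = 1024L),
    small = list(dState = 16L, nLayers = 6L, target = 1.3e6),
    base  = list(dState = 16L, nLayers = 12L, target = 10.1e6))
  if (!is.null(base$target)) {
    cand <- seq(64L, 1024L, by = 8L)
    counts <- vapply(cand, function(d) .ssmParamCount(
      d, base$dState, base$nLayers, 128L, 6L), numeric(1L))
    base$dModel <- cand[which.min(abs(counts - base$target))]
    base$target <- NULL
  }
  do.call(ssmConfig, utils::modifyList(base, list(...)))
}

.ssmParamCount <- function(d, n, nl, projDim, tracks) {
  perLayer <- 3 * d^2 + 3 * d * n + 3 * d + 2 * n
  tracks * d + d + nl * perLayer + d^2 + d + d * projDim + projDim +
    4 * d + 4
}

#' Number of trainable parameters of an encoder
#'
#' @param encoder an \linkS4class{RNAEncoder}.
#' @return integer count.
#' @export
parameterCount <- function(encoder) {
  cnt <- function(x) {
    if (is.list(x)) sum(vapply(x, cnt, numeric(1L)))
    else if (is.numeric(x)) length(x)
    else 0
  }
  cnt(encoder@params)
}

# ---- batching -------------------------------------------------------------

#' Pad a list of encodings into a batch
#'
#' @param encs list of \linkS4class{SixTrackEncoding}.
#' @param tracks number of input tracks used.
#' @return list with \code{X} a (B, L, tracks) array and \code{mask} a
#'   (B, L) logical matrix; padding positions are all-zero and masked.
#' @export
padBatch <- function(encs, tracks = 6L) {
  B <- length(encs)
  Ls <- vapply(encs, length, integer(1L))
  L <- max(Ls)
  X <- array(0, dim = c(B, L, tracks))
  mask <- matrix(FALSE, B, L)
  for (b in seq_len(B)) {
    m <- trackMatrix(encs[[b]])[, seq_len(tracks), drop = FALSE]
    X[b, seq_len(Ls[b]), ] <- m
    mask[b, seq_len(Ls[b])] <- validMask(encs[[b]])
  }
  list(X = X, mask = mask)
}

# ---- SSM forward / backward ----------------------------------------------
# All per-position tensors are flat (B*L) x k column-major matrices with
# row index b + B*(t-1); the C++ scan kernel consumes them directly.

# Forward through the stacked SSM blocks.  Ufl is the flat (B*L) x d
# running representation; each block caches what backward needs.
.ssmForward <- function(params, X, mask, wantCache = FALSE) {
  B <- dim(X)[1L]; L <- dim(X)[2L]
  X[array(!mask, dim(X))] <- 0
  X0 <- matrix(X, B * L, dim(X)[3L])
  U <- sweep(X0 %*% params$W_in, 2L, params$b_in, "+")
  caches <- if (wantCache) vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    p <- params$layers[[l]]
    dpre <- sweep(U %*% p$W_dt, 2L, p$b_dt, "+")
    delta <- .softplus(dpre)
    Bsel <- sweep(U %*% p$W_B, 2L, p$b_B, "+")
    Csel <- sweep(U %*% p$W_C, 2L, p$b_C, "+")
    A <- -exp(p$A_log)
    sc <- scan_fwd_cpp(U, delta, Bsel, Csel, A, B, isTRUE(wantCache))
    Y <- sc$Y
    gpre <- sweep(U %*% p$W_g, 2L, p$b_g, "+")
    g <- gpre * .sigmoid(gpre)
    O <- sweep((Y * g) %*% p$W_o, 2L, p$b_o, "+")
    out <- U + O
    if (wantCache)
      caches[[l]] <- list(U = U, dpre = dpre, delta = delta, Bsel = Bsel,
                          Csel = Csel, A = A, state = sc$state,
                          Y = Y, gpre = gpre, g = g)
    U <- out
  }
  list(hidden = U, X0 = X0, caches = caches, B = B, L = L)
}

.ssmBackward <- function(params, fwd, dHidden) {
  B <- fwd$B; L <- fwd$L
  grads <- list(layers = vector("list", length(params$layers)))
  dU <- dHidden
  for (l in rev(seq_along(params$layers))) {
    p <- params$layers[[l]]
    cc <- fwd$caches[[l]]
    dO <- dU
    Yg <- cc$Y * cc$g
    gW_o <- crossprod(Yg, dO); gb_o <- colSums(dO)
    dYg <- dO %*% t(p$W_o)
    dY <- dYg * cc$g
    dG <- dYg * cc$Y
    sg <- .sigmoid(cc$gpre)
    dGpre <- dG * (sg * (1 + cc$gpre * (1 - sg)))
    gW_g <- crossprod(cc$U, dGpre); gb_g <- colSums(dGpre)
    dUl <- dO + dGpre %*% t(p$W_g)   # residual + gate path
    bw <- scan_bwd_cpp(cc$U, cc$delta, cc$Bsel, cc$Csel, cc$A, cc$state,
                       B, dY)
    dUl <- dUl + bw$dX
    dDpre <- bw$dDelta * .sigmoid(cc$dpre)
    dBsel <- bw$dB
    dCsel <- bw$dC
    selective <- params$selectiveFlag %||% TRUE
    grads$layers[[l]] <- list(
      W_dt = if (selective) crossprod(cc$U, dDpre) else p$W_dt * 0,
      b_dt = colSums(dDpre),
      W_B = if (selective) crossprod(cc$U, dBsel) else p$W_B * 0,
      b_B = colSums(dBsel),
      W_C = if (selective) crossprod(cc$U, dCsel) else p$W_C * 0,
      b_C = colSums(dCsel),
      A_log = bw$dA * cc$A,
      W_g = gW_g, b_g = gb_g, W_o = gW_o, b_o = gb_o)
    if (selective)
      dUl <- dUl + dDpre %*% t(p$W_dt) + dBsel %*% t(p$W_B) +
        dCsel %*% t(p$W_C)
    dU <- dUl
  }
  grads$W_in <- crossprod(fwd$X0, dU)
  grads$b_in <- colSums(dU)
  grads
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Masked pooling of flat hidden states to per-sequence embeddings.
.poolEmbedding <- function(hidden, mask, pooling = "mean") {
  B <- nrow(mask); L <- ncol(mask); d <- ncol(hidden)
  emb <- matrix(0, B, d)
  for (b in seq_len(B)) {
    rows <- b + B * (which(mask[b, ]) - 1L)
    hb <- hidden[rows, , drop = FALSE]
    emb[b, ] <- if (pooling == "max") apply(hb, 2L, max) else colMeans(hb)
  }
  emb
}

.poolBackward <- function(dEmb, mask) {
  B <- nrow(mask); L <- ncol(mask); d <- ncol(dEmb)
  dH <- matrix(0, B * L, d)
  for (b in seq_len(B)) {
    tv <- which(mask[b, ])
    rows <- b + B * (tv - 1L)
    dH[rows, ] <- matrix(dEmb[b, ] / length(tv), length(tv), d, byrow = TRUE)
  }
  dH
}

#' Encode one transcript
#'
#' Runs the encoder over a six-track encoding and returns both the
#' per-position hidden states and the pooled fixed-length embedding
#' (the masked mean of hidden states over valid positions by default).
#' Deterministic: the same input always yields the same output.
#'
#' @param encoder an \linkS4class{RNAEncoder}.
#' @param enc a \linkS4class{SixTrackEncoding}.
#' @return list with \code{hidden} (L x dModel matrix) and
#'   \code{embedding} (length-dModel vector).
#' @export
encodeSequence <- function(encoder, enc) {
  if (length(enc) > encoder@config$maxLen)
    stop("encoding longer than the configured maxLen")
  if (ncol(trackMatrix(enc)) < encoder@config$inputTracks)
    stop("track count does not match encoder config")
  out <- encodeBatch(encoder, list(enc))
  list(hidden = out$hidden[[1L]], embedding = out$embeddings[1L, ])
}

#' Encode a batch of transcripts
#'
#' @param encoder an \linkS4class{RNAEncoder}.
#' @param encs list of \linkS4class{SixTrackEncoding}.
#' @return list with \code{embeddings} (B x dModel matrix) and
#'   \code{hidden} (list of L_b x dModel matrices).
#' @export
encodeBatch <- function(encoder, encs) {
  pb <- padBatch(encs, encoder@config$inputTracks)
  if (encoder@kind %in% c("selective", "nonselective")) {
    fwd <- .ssmForward(encoder@params, pb$X, pb$mask)
    hid <- fwd$hidden
  } else {
    hid <- .baselineForward(encoder, pb$X, pb$mask)
  }
  emb <- .poolEmbedding(hid, pb$mask, encoder@config$pooling)
  B <- nrow(pb$mask)
  hiddenList <- lapply(seq_len(B), function(b) {
    rows <- b + B * (which(pb$mask[b, ]) - 1L)
    hid[rows, , drop = FALSE]
  })
  list(embeddings = emb, hidden = hiddenList)
}

#' Project an embedding through the contrastive head
#'
#' Two-layer perceptron followed by L2 normalization; used only during
#' pre-training (the projector is discarded for downstream evaluation).
#'
#' @param encoder an \linkS4class{RNAEncoder} (selective/nonselective).
#' @param h embedding vector or B x dModel matrix.
#' @return unit-norm projection(s), same orientation as the input.
#' @export
projectEmbedding <- function(encoder, h) {
  vec <- is.null(dim(h))
  hm <- if (vec) matrix(h, 1L) else h
  p <- encoder@params
  a <- pmax(sweep(hm %*% p$W_p1, 2L, p$b_p1, "+"), 0)
  v <- sweep(a %*% p$W_p2, 2L, p$b_p2, "+")
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm < 1e-12)) stop("projection collapsed to the zero vector")
  z <- v / nrm
  if (vec) z[1L, ] else z
}

# Projection forward with cache plus backward, used by the trainer.
.projForward <- function(p, hm) {
  apre <- sweep(hm %*% p$W_p1, 2L, p$b_p1, "+")
  a <- pmax(apre, 0)
  v <- sweep(a %*% p$W_p2, 2L, p$b_p2, "+")
  nrm <- sqrt(rowSums(v^2))
  nrm <- pmax(nrm, 1e-12)
  list(z = v / nrm, v = v, nrm = nrm, a = a, apre = apre, hm = hm)
}

.projBackward <- function(p, cache, dZ) {
  z <- cache$z
  dv <- (dZ - z * rowSums(dZ * z)) / cache$nrm
  gW_p2 <- crossprod(cache$a, dv); gb_p2 <- colSums(dv)
  da <- dv %*% t(p$W_p2)
  da[cache$apre <= 0] <- 0
  gW_p1 <- crossprod(cache$hm, da); gb_p1 <- colSums(da)
  dH <- da %*% t(p$W_p1)
  list(dH = dH,
       grads = list(W_p1 = gW_p1, b_p1 = gb_p1, W_p2 = gW_p2, b_p2 = gb_p2))
}

# ---- baseline encoders ----------------------------------------------------

.initDilatedCNN <- function(cfg, seed) {
  withr::with_seed(seed, {
    d <- cfg$dModel
    nl <- cfg$nLayers
    layers <- lapply(seq_len(nl), function(l) list(
      W = array(stats::rnorm(3 * d * d, sd = 1 / sqrt(3 * d)), c(3L, d, d)),
      b = rep(0, d), dilation = as.integer(2^(l - 1L))))
    list(W_in = .rmat(cfg$inputTracks, d, 1 / sqrt(cfg$inputTracks)),
         b_in = rep(0, d), layers = layers,
         W_p1 = .rmat(d, d, 1 / sqrt(d)), b_p1 = rep(0, d),
         W_p2 = .rmat(d, cfg$projDim, 1 / sqrt(d)),
         b_p2 = rep(0, cfg$projDim))
  })
}

.initCNNRNN <- function(cfg, seed) {
  withr::with_seed(seed, {
    d <- cfg$dModel
    list(W_in = .rmat(cfg$inputTracks, d, 1 / sqrt(cfg$inputTracks)),
         b_in = rep(0, d),
         conv = list(W = array(stats::rnorm(5 * d * d, sd = 1 / sqrt(5 * d)),
                               c(5L, d, d)), b = rep(0, d)),
         W_h = .rmat(d, d, 1 / sqrt(d)), W_x = .rmat(d, d, 1 / sqrt(d)),
         b_h = rep(0, d),
         W_p1 = .rmat(d, d, 1 / sqrt(d)), b_p1 = rep(0, d),
         W_p2 = .rmat(d, cfg$projDim, 1 / sqrt(d)),
         b_p2 = rep(0, cfg$projDim))
  })
}

# Zero-padded 1-D convolution along time for a (B*L) x d flat matrix.
.conv1d <- function(U, B, L, W, b, dilation = 1L) {
  k <- dim(W)[1L]
  half <- (k - 1L) %/% 2L
  out <- matrix(rep(b, each = B * L), B * L, length(b))
  for (o in seq_len(k)) {
    shift <- (o - 1L - half) * dilation
    tsrc <- seq_len(L) + shift
    ok <- tsrc >= 1L & tsrc <= L
    if (!any(ok)) next
    rowsDst <- as.vector(outer(seq_len(B), B * (which(ok) - 1L), "+"))
    rowsSrc <- as.vector(outer(seq_len(B), B * (tsrc[ok] - 1L), "+"))
    out[rowsDst, ] <- out[rowsDst, , drop = FALSE] +
      U[rowsSrc, , drop = FALSE] %*% W[o, , ]
  }
  out
}

.baselineForward <- function(encoder, X, mask) {
  p <- encoder@params
  B <- dim(X)[1L]; L <- dim(X)[2L]
  X[array(!mask, dim(X))] <- 0
  U <- sweep(matrix(X, B * L, dim(X)[3L]) %*% p$W_in, 2L, p$b_in, "+")
  if (encoder@kind == "dilated_cnn") {
    for (lp in p$layers)
      U <- U + pmax(.conv1d(U, B, L, lp$W, lp$b, lp$dilation), 0)
  } else {
    U <- pmax(.conv1d(U, B, L, p$conv$W, p$conv$b), 0)
    H <- matrix(0, B, ncol(U))
    out <- matrix(0, B * L, ncol(U))
    for (t in seq_len(L)) {
      rows <- seq_len(B) + B * (t - 1L)
      H <- tanh(U[rows, , drop = FALSE] %*% p$W_x + H %*% p$W_h +
                matrix(p$b_h, B, length(p$b_h), byrow = TRUE))
      out[rows, ] <- H
    }
    U <- out
  }
  U
}

#' Receptive field of a dilated CNN encoder
#'
#' @param encoder a \code{dilated_cnn} \linkS4class{RNAEncoder}.
#' @return receptive field width in positions (grows geometrically with
#'   depth).
#' @export
receptiveField <- function(encoder) {
  stopifnot(encoder@kind == "dilated_cnn")
  1L + sum(vapply(encoder@params$layers,
                  function(l) 2L * l$dilation, integer(1L)))
}
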