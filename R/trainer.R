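#' Pre-training configuration
#'
#' @param batchSize contrastive batch size N (>= 2 for any contrastive
#'   objective; larger batches supply more negatives).
#' @param epochs number of passes over the reference transcripts;
#'   positive pairs are re-sampled every epoch.
#' @param lr peak learning rate (cosine-decayed over training).
#' @param weightDecay decoupled weight decay applied to weight matrices.
#' @param seed RNG seed controlling shuffling, pair sampling and MLM
#'   masks.
#' @param objective \code{"cl"}, \code{"mlm"} or \code{"cl+mlm"}.
#' @param alpha CL/MLM mixing weight (used for \code{"cl+mlm"}).
#' @param temperature DCL temperature.
#' @param orthologyWeight positive-pair weight for orthology draws.
#' @param maskFraction masking-augmentation fraction.
#' @param includeMasking include the masked reference in each
#'   reference's union of augmentation sources (the full four-source
#'   augmentation scheme), not only as the empty-set fallback.
#' @param mlmFraction MLM corruption fraction.
#' @param maxLen encoding length cap during training.
#' @param geneExclusive if TRUE (default) at most one reference per
#'   gene is placed in a batch, avoiding same-gene false negatives;
#'   FALSE reproduces plain shuffled batching.
#' @param checkpointDir optional directory for epoch checkpoints.
#' @return a \code{train_config} list.
#' @export
trainConfig <- function(batchSize = 16L, epochs = 3L, lr = 1e-3,
                        weightDecay = 0.01, seed = 1L,
                        objective = c("cl", "mlm", "cl+mlm"),
                        alpha = 0.95, temperature = 0.1,
                        orthologyWeight = 0.8, maskFraction = 0.30,
                        mlmFraction = 0.15, maxLen = 1536L,
                        geneExclusive = TRUE, includeMasking = TRUE,
                        checkpointDir = NULL) {
  objective <- match.arg(objective)
  if (objective != "mlm" && batchSize < 2L)
    stop("contrastive objectives need batchSize >= 2")
  cfg <- list(batchSize = as.integer(batchSize), epochs = as.integer(epochs),
              lr = lr, weightDecay = weightDecay, seed = as.integer(seed),
              objective = objective, alpha = alpha,
              temperature = temperature, orthologyWeight = orthologyWeight,
              maskFraction = maskFraction, mlmFraction = mlmFraction,
              maxLen = as.integer(maxLen),
              geneExclusive = isTRUE(geneExclusive),
              includeMasking = isTRUE(includeMasking),
              checkpointDir = checkpointDir)
  class(cfg) <- "train_config"
  cfg
}

#' Assemble per-epoch batches of reference transcripts
#'
#' References are shuffled deterministically per (seed, epoch). In
#' gene-exclusive mode a reference is never batched with another
#' isoform of the same gene (those would be false negatives for the
#' contrastive loss).
#'
#' @param referenceIds character vector of reference transcript ids.
#' @param geneIds gene id per reference (same order).
#' @param epoch epoch number.
#' @param cfg a \code{\link{trainConfig}}.
#' @return list of character vectors (batches).
#' @export
makeBatches <- function(referenceIds, geneIds, epoch, cfg) {
  n <- length(referenceIds)
  if (n < cfg$batchSize)
    warning("fewer references than batchSize; emitting one smaller batch")
  ord <- withr::with_seed(.stableHash(cfg$seed, epoch, "shuffle"),
                          sample.int(n))
  ids <- referenceIds[ord]; genes <- geneIds[ord]
  if (!cfg$geneExclusive) {
    return(split(ids, ceiling(seq_len(n) / cfg$batchSize)))
  }
  batches <- list(); batchGenes <- list()
  for (i in seq_len(n)) {
    placed <- FALSE
    for (b in seq_along(batches)) {
      if (length(batches[[b]]) < cfg$batchSize &&
          !(genes[i] %in% batchGenes[[b]])) {
        batches[[b]] <- c(batches[[b]], ids[i])
        batchGenes[[b]] <- c(batchGenes[[b]], genes[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      batches[[length(batches) + 1L]] <- ids[i]
      batchGenes[[length(batchGenes) + 1L]] <- genes[i]
    }
  }
  unname(batches)
}

# ---- AdamW over nested parameter lists -----------------------------------

.mapLeaves <- function(f, ...) {
  args <- list(...)
  p <- args[[1L]]
  if (is.list(p))
    return(stats::setNames(lapply(seq_along(p), function(i)
      do.call(.mapLeaves, c(list(f), lapply(args, `[[`, i)))), names(p)))
  if (!is.numeric(p)) return(p)
  do.call(f, args)
}

.zeroLike <- function(p) .mapLeaves(function(x) x * 0, p)

.adamInit <- function(params) list(m = .zeroLike(params),
                                   v = .zeroLike(params), t = 0L)

.adamStep <- function(opt, params, grads, lr, weightDecay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  t <- opt$t
  opt$m <- .mapLeaves(function(m, g) beta1 * m + (1 - beta1) * g,
                      opt$m, grads)
  opt$v <- .mapLeaves(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      opt$v, grads)
  corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
  params <- .mapLeaves(function(p, m, v) {
    upd <- (m / corr1) / (sqrt(v / corr2) + eps)
    wd <- if (is.matrix(p)) weightDecay else 0
    p - lr * (upd + wd * p)
  }, params, opt$m, opt$v)
  list(opt = opt, params = params)
}

# Align grads structure to params (missing leaves get zero gradient).
.gradsLike <- function(params, grads) {
  if (is.list(params)) {
    out <- lapply(names(params) %||% seq_along(params), function(k)
      .gradsLike(params[[k]],
                 if (!is.null(grads)) grads[[k]] else NULL))
    names(out) <- names(params)
    return(out)
  }
  if (!is.numeric(params)) return(params)
  if (is.null(grads)) params * 0 else grads
}

.addGrads <- function(a, b) .mapLeaves(function(x, y) x + y, a, b)

# ---- the pre-training loop ------------------------------------------------

# Forward + backward for one batch under the configured objective.
# Returns loss components and parameter gradients.
.batchStep <- function(params, cfg, encCfg, pairs, step) {
  B <- length(pairs)
  weights <- vapply(pairs, `[[`, numeric(1L), "weight")
  x1 <- lapply(pairs, `[[`, "x1")
  doCL <- cfg$objective != "mlm"
  doMLM <- cfg$objective != "cl"
  lcl <- NA_real_; lmlm <- NA_real_
  grads <- NULL
  mlmInfo <- NULL
  if (doMLM) {
    corr <- lapply(seq_len(B), function(b)
      applyMlmCorruption(x1[[b]], cfg$mlmFraction,
                         seed = .stableHash(cfg$seed, step, b, "mlm")))
    targets1 <- lapply(x1, function(e) trackMatrix(e)[, 1:4, drop = FALSE])
    x1 <- lapply(corr, `[[`, "corrupted")
    mlmInfo <- list(masks = lapply(corr, `[[`, "maskedPositions"),
                    targets = targets1)
  }
  pb1 <- padBatch(x1, encCfg$inputTracks)
  fwd1 <- .ssmForward(params, pb1$X, pb1$mask, wantCache = TRUE)
  dHid1 <- matrix(0, nrow(fwd1$hidden), ncol(fwd1$hidden))
  if (doCL) {
    x2 <- lapply(pairs, `[[`, "x2")
    pb2 <- padBatch(x2, encCfg$inputTracks)
    fwd2 <- .ssmForward(params, pb2$X, pb2$mask, wantCache = TRUE)
    emb1 <- .poolEmbedding(fwd1$hidden, pb1$mask, encCfg$pooling)
    emb2 <- .poolEmbedding(fwd2$hidden, pb2$mask, encCfg$pooling)
    pj1 <- .projForward(params, emb1)
    pj2 <- .projForward(params, emb2)
    dcl <- dclLossGrad(pj1$z, pj2$z, weights, cfg$temperature)
    lcl <- dcl$loss
    bw1 <- .projBackward(params, pj1, dcl$dZ1)
    bw2 <- .projBackward(params, pj2, dcl$dZ2)
    sc <- if (cfg$objective == "cl+mlm") (1 - cfg$alpha) else 1
    dHid1 <- dHid1 + sc * .poolBackward(bw1$dH, pb1$mask)
    dHid2 <- sc * .poolBackward(bw2$dH, pb2$mask)
    g2 <- .ssmBackward(params, fwd2, dHid2)
    projG <- .mapLeaves(function(a, b) sc * (a + b),
                        bw1$grads, bw2$grads)
    grads <- .addGrads(.gradsLike(params, g2), .gradsLike(params, projG))
  }
  if (doMLM) {
    Bn <- nrow(pb1$mask)
    logits <- sweep(fwd1$hidden %*% params$W_mlm, 2L, params$b_mlm, "+")
    mx <- apply(logits, 1L, max)
    P <- exp(logits - mx); P <- P / rowSums(P)
    lossSum <- 0; dLogits <- matrix(0, nrow(logits), 4L)
    for (b in seq_len(Bn)) {
      mpos <- mlmInfo$masks[[b]]
      if (!length(mpos)) next
      rows <- b + Bn * (mpos - 1L)
      Tm <- mlmInfo$targets[[b]][mpos, , drop = FALSE]
      present <- rowSums(Tm) > 0
      Pm <- P[rows, , drop = FALSE]
      hit <- pmax(rowSums(Tm * Pm), 1e-12)
      lossSum <- lossSum - sum(log(hit[present])) / length(mpos)
      dL <- (Pm - Tm) / length(mpos) / Bn
      dL[!present, ] <- 0
      dLogits[rows, ] <- dL
    }
    lmlm <- lossSum / Bn
    sc <- if (cfg$objective == "cl+mlm") cfg$alpha else 1
    dLogits <- dLogits * sc
    headG <- list(W_mlm = crossprod(fwd1$hidden, dLogits),
                  b_mlm = colSums(dLogits))
    dHid1 <- dHid1 + dLogits %*% t(params$W_mlm)
    grads <- if (is.null(grads)) .gradsLike(params, headG)
             else .addGrads(grads, .gradsLike(params, headG))
  }
  g1 <- .ssmBackward(params, fwd1, dHid1)
  grads <- .addGrads(grads, .gradsLike(params, g1))
  ltotal <- if (cfg$objective == "cl+mlm")
    (1 - cfg$alpha) * lcl + cfg$alpha * lmlm
  else if (cfg$objective == "cl") lcl else lmlm
  list(lcl = lcl, lmlm = lmlm, ltotal = ltotal, grads = grads)
}

#' Pre-train an encoder on a contrastive pair corpus
#'
#' Ties together pair sampling, the shared encoder, the projection
#' head and the losses. Per-step losses are logged; checkpoints are
#' written at epoch boundaries when a checkpoint directory is
#' configured. Training aborts with a diagnostic on a non-finite loss.
#'
#' @param corpus a \code{synthetic_corpus} (or any list with
#'   \code{rnas} and \code{labels} of the same shape).
#' @param cfg a \code{\link{trainConfig}}.
#' @param encoder an \linkS4class{RNAEncoder} to start from; defaults
#'   to a freshly initialized micro selective encoder.
#' @param sets an \linkS4class{AugmentationSets}; defaults to
#'   splicing + orthology sets built from the corpus.
#' @param resume a \code{train_state} returned by a previous call, to
#'   continue training bit-identically.
#' @return a \code{train_state} list: \code{encoder} (trained),
#'   \code{log} (data.frame with step, epoch, l_cl, l_mlm, l_total),
#'   \code{opt}, \code{cfg}, \code{epoch}.
#' @export
pretrain <- function(corpus, cfg = trainConfig(), encoder = NULL,
                     sets = NULL, resume = NULL) {
  lb <- corpus$labels[corpus$labels$species == "ref", ]
  refIds <- lb$transcriptId
  geneIds <- lb$geneId
  if (is.null(sets)) {
    spOf <- vapply(corpus$models, speciesId, character(1L))
    sets <- buildSplicingSets(corpus$models[spOf == "ref"])
    if (nrow(corpus$mapping))
      sets <- buildOrthologySets(sets, corpus$mapping,
                                 corpus$models[spOf != "ref"],
                                 corpus$rnas)
  }
  if (!is.null(resume)) {
    params <- resume$encoder@params
    opt <- resume$opt
    encoder <- resume$encoder
    startEpoch <- resume$epoch + 1L
    log <- resume$log
  } else {
    if (is.null(encoder))
      encoder <- buildEncoder("selective",
                              presetConfig("micro", maxLen = cfg$maxLen),
                              seed = cfg$seed)
    params <- encoder@params
    opt <- .adamInit(params)
    startEpoch <- 1L
    log <- NULL
  }
  encCfg <- encoder@config
  nBatchesPerEpoch <- ceiling(length(refIds) / cfg$batchSize)
  totalSteps <- cfg$epochs * nBatchesPerEpoch
  step <- (startEpoch - 1L) * nBatchesPerEpoch
  logRows <- list()
  for (epoch in startEpoch:cfg$epochs) {
    batches <- makeBatches(refIds, geneIds, epoch, cfg)
    for (batch in batches) {
      step <- step + 1L
      pairs <- lapply(batch, function(id)
        samplePositivePair(id, sets, corpus$rnas, epoch, cfg$seed,
                           cfg$orthologyWeight, cfg$maskFraction,
                           cfg$maxLen, cfg$includeMasking %||% FALSE))
      if (cfg$objective != "mlm" && length(pairs) < 2L) next
      res <- .batchStep(params, cfg, encCfg, pairs, step)
      if (!is.finite(res$ltotal))
        stop(sprintf("non-finite loss at step %d (batch: %s)", step,
                     paste(batch, collapse = ",")))
      lrT <- cfg$lr * 0.5 * (1 + cos(pi * (step - 1) / max(1, totalSteps)))
      ad <- .adamStep(opt, params, res$grads, lrT, cfg$weightDecay)
      opt <- ad$opt; params <- ad$params
      logRows[[length(logRows) + 1L]] <- data.frame(
        step = step, epoch = epoch, l_cl = res$lcl, l_mlm = res$lmlm,
        l_total = res$ltotal)
    }
    if (!is.null(cfg$checkpointDir)) {
      dir.create(cfg$checkpointDir, showWarnings = FALSE, recursive = TRUE)
      enc <- new("RNAEncoder", kind = encoder@kind, config = encCfg,
                 params = params)
      saveRDS(list(encoder = enc, opt = opt, epoch = epoch, cfg = cfg),
              file.path(cfg$checkpointDir, sprintf("epoch_%03d.rds", epoch)))
    }
  }
  newLog <- do.call(rbind, logRows)
  if (cfg$objective == "cl") newLog$l_mlm <- NULL
  if (cfg$objective == "mlm") newLog$l_cl <- NULL
  out <- list(encoder = new("RNAEncoder", kind = encoder@kind,
                            config = encCfg, params = params),
              log = if (is.null(log)) newLog else rbind(log, newLog),
              opt = opt, cfg = cfg, epoch = cfg$epochs)
  class(out) <- "train_state"
  out
}

#' Embed a set of mature RNAs
#'
#' @param encoder an \linkS4class{RNAEncoder}.
#' @param rnas named list of \linkS4class{MatureRNA}.
#' @param maxLen encoding length cap (defaults to the encoder's).
#' @param batchSize sequences per forward pass.
#' @return matrix of embeddings, one row per transcript, rownames set
#'   to transcript ids.
#' @export
embedCorpus <- function(encoder, rnas, maxLen = NULL, batchSize = 32L) {
  if (is.null(maxLen)) maxLen <- encoder@config$maxLen
  ids <- names(rnas)
  lens <- vapply(rnas, length, integer(1L))
  ord <- order(lens)                       # length-sorted batches pad less
  emb <- matrix(0, length(rnas), encoder@config$dModel,
                dimnames = list(ids, NULL))
  i <- 1L
  while (i <= length(ord)) {
    idx <- ord[i:min(i + batchSize - 1L, length(ord))]
    encs <- lapply(rnas[idx], encodeSixTrack, maxLen = maxLen)
    emb[idx, ] <- encodeBatch(encoder, encs)$embeddings
    i <- i + batchSize
  }
  emb
}

# ---- selective copying benchmark -----------------------------------------

#' Generate a selective-copying batch
#'
#' Each sequence of length \code{L} carries \code{k} data tokens (from
#' a 4-letter vocabulary) at random positions among noise positions; the
#' final \code{k} positions are output cues at which the model must
#' reproduce the data tokens in order. Inputs use the six-track layout:
#' tracks 1-4 one-hot the data token, track 5 marks noise positions and
#' track 6 marks the output cues.
#'
#' @param nSeq number of sequences.
#' @param L sequence length.
#' @param k number of data tokens.
#' @param seed RNG seed.
#' @return list with \code{X} (nSeq, L, 6) array, \code{mask}, and
#'   \code{targets} (nSeq x k token-index matrix).
#' @export
selectiveCopyTask <- function(nSeq, L = 64L, k = 4L, seed = 1L) {
  withr::with_seed(seed, {
    X <- array(0, c(nSeq, L, 6L))
    targets <- matrix(0L, nSeq, k)
    for (b in seq_len(nSeq)) {
      pos <- sort(sample(seq_len(L - k), k))
      tok <- sample(1:4, k, replace = TRUE)
      X[b, , 5L] <- 1
      for (j in seq_len(k)) {
        X[b, pos[j], tok[j]] <- 1
        X[b, pos[j], 5L] <- 0
      }
      X[b, (L - k + 1L):L, 5L] <- 0
      X[b, (L - k + 1L):L, 6L] <- 1
      targets[b, ] <- tok
    }
    list(X = X, mask = matrix(TRUE, nSeq, L), targets = targets)
  })
}

#' Train an encoder on the selective-copying task
#'
#' Demonstrates the content-based routing that input-dependent
#' (selective) state-space parameters buy: a small selective model
#' solves the task while a parameter-matched non-selective (LTI)
#' variant cannot, because it has no way to distinguish data tokens
#' from noise at arbitrary offsets.
#'
#' @param selective train the selective (TRUE) or non-selective
#'   variant.
#' @param steps optimization steps.
#' @param batchSize sequences per step.
#' @param L sequence length.
#' @param k data tokens per sequence.
#' @param dModel,dState,nLayers encoder dimensions.
#' @param lr learning rate.
#' @param seed RNG seed.
#' @return list with \code{accuracy} (held-out token accuracy),
#'   \code{log} (per-step loss data.frame), \code{encoder}.
#' @export
trainSelectiveCopy <- function(selective = TRUE, steps = 500L,
                               batchSize = 32L, L = 64L, k = 4L,
                               dModel = 64L, dState = 8L, nLayers = 2L,
                               lr = 3e-3, seed = 1L) {
  cfgE <- ssmConfig(dModel = dModel, dState = dState, nLayers = nLayers,
                    maxLen = L, selective = selective)
  enc <- buildEncoder(if (selective) "selective" else "nonselective",
                      cfgE, seed = seed)
  params <- enc@params
  opt <- .adamInit(params)
  logRows <- numeric(steps)
  for (s in seq_len(steps)) {
    task <- selectiveCopyTask(batchSize, L, k, seed = seed * 100000L + s)
    fwd <- .ssmForward(params, task$X, task$mask, wantCache = TRUE)
    B <- batchSize
    logits <- sweep(fwd$hidden %*% params$W_mlm, 2L, params$b_mlm, "+")
    mx <- apply(logits, 1L, max)
    P <- exp(logits - mx); P <- P / rowSums(P)
    rows <- as.vector(vapply(seq_len(k), function(j)
      as.integer(seq_len(B) + B * (L - k + j - 1L)), integer(B)))
    tgt <- as.vector(task$targets)
    hit <- P[cbind(rows, tgt)]
    loss <- -mean(log(pmax(hit, 1e-12)))
    dLogits <- matrix(0, nrow(logits), 4L)
    dP <- P[rows, , drop = FALSE]
    dP[cbind(seq_along(rows), tgt)] <- dP[cbind(seq_along(rows), tgt)] - 1
    dLogits[rows, ] <- dP / length(rows)
    headG <- list(W_mlm = crossprod(fwd$hidden, dLogits),
                  b_mlm = colSums(dLogits))
    dHid <- dLogits %*% t(params$W_mlm)
    g <- .ssmBackward(params, fwd, dHid)
    grads <- .addGrads(.gradsLike(params, g), .gradsLike(params, headG))
    lrT <- lr * 0.5 * (1 + cos(pi * (s - 1) / steps))
    ad <- .adamStep(opt, params, grads, lrT, weightDecay = 0)
    opt <- ad$opt; params <- ad$params
    logRows[s] <- loss
  }
  test <- selectiveCopyTask(256L, L, k, seed = seed + 777L)
  fwd <- .ssmForward(params, test$X, test$mask)
  logits <- sweep(fwd$hidden %*% params$W_mlm, 2L, params$b_mlm, "+")
  B <- 256L
  rows <- as.vector(vapply(seq_len(k), function(j)
    as.integer(seq_len(B) + B * (L - k + j - 1L)), integer(B)))
  pred <- max.col(logits[rows, , drop = FALSE])
  acc <- mean(pred == as.vector(test$targets))
  list(accuracy = acc,
       log = data.frame(step = seq_len(steps), loss = logRows),
       encoder = new("RNAEncoder", kind = enc@kind, config = unclass(cfgE),
                     params = params))
}
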