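#' Homology-aware train/validation/test split
#'
#' Whole gene families are assigned to exactly one partition so that no
#' homologous sequences straddle the split. Families are shuffled
#' deterministically per seed and assigned greedily to the partition
#' with the largest remaining deficit relative to the target fractions.
#'
#' @param ids transcript ids.
#' @param familyIds family id per transcript (same order).
#' @param fractions length-3 numeric summing to 1 (train, val, test).
#' @param seed RNG seed.
#' @return list with \code{train}, \code{val}, \code{test} id vectors.
#' @export
homologySplit <- function(ids, familyIds, fractions = c(0.8, 0.1, 0.1),
                          seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  fams <- split(ids, familyIds)
  ord <- withr::with_seed(seed, sample(names(fams)))
  n <- length(ids)
  target <- fractions * n
  assigned <- c(0, 0, 0)
  part <- list(character(), character(), character())
  for (f in ord) {
    sz <- length(fams[[f]])
    if (sz > max(target))
      warning("family ", f, " is larger than a partition target; assigned anyway")
    deficit <- (target - assigned) / pmax(target, 1e-9)
    k <- which.max(deficit)
    part[[k]] <- c(part[[k]], fams[[f]])
    assigned[k] <- assigned[k] + sz
  }
  list(train = part[[1L]], val = part[[2L]], test = part[[3L]])
}

#' Subsample a training set for few-shot evaluation
#'
#' @param trainIds training transcript ids.
#' @param n number of examples to keep (e.g. 30, 100, 300).
#' @param seed RNG seed.
#' @return a uniform without-replacement subsample, deterministic per
#'   seed; validation/test sets are untouched by construction.
#' @export
fewShotSubsample <- function(trainIds, n, seed = 1L) {
  if (n > length(trainIds)) stop("n exceeds the training-set size")
  if (n == length(trainIds)) return(trainIds)
  withr::with_seed(seed, sample(trainIds, n))
}

# Average precision (area under the precision-recall curve by the
# standard step interpolation): mean of precision at each positive.
.averagePrecision <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  if (!any(lab)) return(NA_real_)
  cum <- cumsum(lab)
  prec <- cum / seq_along(lab)
  sum(prec[lab]) / sum(lab)
}

#' Fit a linear probe on frozen embeddings
#'
#' Trains a ridge-regularized linear map (regression) or a regularized
#' logistic map (classification) on frozen embeddings, selecting the
#' regularization strength on the validation partition from a grid of 7
#' log-spaced values, and reports the test metric: Pearson's R for
#' regression, auPRC for classification (macro-averaged over classes
#' for multi-class tasks).
#'
#' @param embeddings numeric matrix with transcript ids as rownames.
#' @param task a \code{probe_task} (see
#'   \code{\link{corpusToProbeTask}}).
#' @param split a \code{\link{homologySplit}} result.
#' @param seed RNG seed (glmnet internals).
#' @return list: \code{value} (test metric), \code{metric} name,
#'   \code{lambda} selected.
#' @export
fitLinearProbe <- function(embeddings, task, split, seed = 1L) {
  lam <- 10^seq(2, -4, length.out = 7L)
  ids <- intersect(names(task$labels), rownames(embeddings))
  tr <- intersect(split$train, ids)
  va <- intersect(split$val, ids)
  te <- intersect(split$test, ids)
  if (length(intersect(tr, te)) || length(intersect(tr, va)))
    stop("split partitions must be disjoint")
  Xtr <- embeddings[tr, , drop = FALSE]
  ytr <- task$labels[tr]
  if (task$kind == "regression") {
    if (stats::sd(ytr) == 0) stop("constant training labels")
    fit <- withr::with_seed(seed, glmnet::glmnet(
      Xtr, ytr, alpha = 0, lambda = lam, family = "gaussian"))
    pv <- stats::predict(fit, embeddings[va, , drop = FALSE])
    mse <- colMeans((pv - task$labels[va])^2)
    k <- which.min(mse)
    pt <- stats::predict(fit, embeddings[te, , drop = FALSE])[, k]
    value <- stats::cor(pt, task$labels[te])
    list(value = unname(value), metric = "pearson_r",
         lambda = fit$lambda[k])
  } else {
    yf <- factor(task$labels[tr])
    if (nlevels(yf) < 2L) stop("need at least two classes in train")
    fam <- if (nlevels(yf) == 2L) "binomial" else "multinomial"
    fit <- withr::with_seed(seed, glmnet::glmnet(
      Xtr, yf, alpha = 0, lambda = lam, family = fam))
    pv <- stats::predict(fit, embeddings[va, , drop = FALSE],
                         type = "response")
    yva <- factor(task$labels[va], levels = levels(yf))
    ll <- vapply(seq_along(lam), function(k) {
      P <- if (fam == "binomial")
        cbind(1 - pv[, k], pv[, k]) else pv[, , k]
      -mean(log(pmax(P[cbind(seq_along(yva), as.integer(yva))], 1e-12)))
    }, numeric(1L))
    k <- which.min(ll)
    pte <- stats::predict(fit, embeddings[te, , drop = FALSE],
                          type = "response")
    Pte <- if (fam == "binomial")
      cbind(1 - pte[, k], pte[, k]) else pte[, , k]
    yte <- factor(task$labels[te], levels = levels(yf))
    aps <- vapply(seq_len(nlevels(yf)), function(cl)
      .averagePrecision(Pte[, cl], as.integer(yte) == cl), numeric(1L))
    list(value = mean(aps, na.rm = TRUE), metric = "auprc",
         lambda = lam[k])
  }
}

#' Fisher Z-transformation
#'
#' Variance-stabilizing arctanh transform of a correlation coefficient,
#' applied to regression metrics before Z-score pooling.
#'
#' @param r correlation value(s), |r| < 1.
#' @return arctanh(r).
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1 for the Fisher transform")
  atanh(r)
}

#' Z-score normalization of probing results for one task
#'
#' Pools the per-seed scores of every configuration into one reference
#' distribution (regression metrics are Fisher-transformed first),
#' converts each score to \code{(x - mu) / sigma}, and averages over
#' seeds per configuration.
#'
#' @param results data.frame with columns \code{config}, \code{seed},
#'   \code{value} (one task).
#' @param kind \code{"regression"} or \code{"classification"}.
#' @return list: \code{table} (config, meanZ, nSeeds), \code{z}
#'   (per-row Z scores), \code{mu}, \code{sigma}.
#' @export
zscoreNormalize <- function(results, kind = c("regression",
                                              "classification")) {
  kind <- match.arg(kind)
  if (length(unique(results$config)) < 2L)
    stop("need at least two configurations to pool a reference")
  if (min(table(results$config)) < 2L)
    stop("need at least two seeds per configuration")
  x <- if (kind == "regression") fisherZ(results$value) else results$value
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))   # population sd, as in numpy's std
  if (sigma == 0) stop("pooled reference has zero variance")
  z <- (x - mu) / sigma
  agg <- stats::aggregate(z, by = list(config = results$config), FUN = mean)
  names(agg)[2L] <- "meanZ"
  agg$nSeeds <- as.integer(table(results$config)[agg$config])
  list(table = agg, z = z, mu = mu, sigma = sigma)
}

#' Aggregate Z-scores across tasks
#'
#' @param results data.frame with columns \code{config}, \code{task},
#'   \code{kind}, \code{seed}, \code{value}.
#' @return list: \code{perTask} (config x task mean Z, long form) and
#'   \code{aggregate} (config, aggregateZ = unweighted mean of task
#'   Z-scores).
#' @export
aggregateZScores <- function(results) {
  rows <- list()
  for (tk in unique(results$task)) {
    sub <- results[results$task == tk, ]
    zn <- zscoreNormalize(sub, kind = sub$kind[1L])
    tt <- zn$table
    tt$task <- tk
    rows[[tk]] <- tt
  }
  perTask <- do.call(rbind, rows)
  rownames(perTask) <- NULL
  agg <- stats::aggregate(perTask$meanZ,
                          by = list(config = perTask$config), FUN = mean)
  names(agg)[2L] <- "aggregateZ"
  list(perTask = perTask, aggregate = agg)
}

#' One-sided Welch's t-test against a reference configuration
#'
#' Tests whether the reference configuration's scores are greater than
#' the candidate's, with unequal variances (Satterthwaite degrees of
#' freedom). A p-value above 0.05 means the candidate is not
#' significantly worse than the reference and is flagged top-tier.
#' A paired variant (samples paired by seed) is available behind
#' \code{paired}.
#'
#' @param reference,candidate numeric score vectors (>= 2 values each).
#' @param paired use a paired t-test (pairs matched by position).
#' @return list: \code{p}, \code{t}, \code{df}, \code{topTier}.
#' @export
welchOneSided <- function(reference, candidate, paired = FALSE) {
  if (length(reference) < 2L || length(candidate) < 2L)
    stop("need at least two values per group")
  if (stats::sd(reference) == 0 && stats::sd(candidate) == 0) {
    # degenerate: no variance anywhere; decide by the means alone
    d <- mean(reference) - mean(candidate)
    p <- if (d == 0) 0.5 else if (d > 0) 0 else 1
    return(list(p = p, t = if (d == 0) 0 else sign(d) * Inf,
                df = NA_real_, topTier = p > 0.05))
  }
  tt <- stats::t.test(reference, candidate, alternative = "greater",
                      var.equal = FALSE, paired = paired)
  list(p = unname(tt$p.value), t = unname(tt$statistic),
       df = unname(tt$parameter), topTier = unname(tt$p.value) > 0.05)
}
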