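#' Embedding similarity score
#'
#' \code{1 - log(L2 distance)} (natural log), so higher scores mean
#' closer embeddings: distance 1 scores 1, distance e scores 0.
#' Distances are floored at 1e-8 so identical embeddings score a
#' finite 1 - log(1e-8) ~ 19.42.
#'
#' @param e1,e2 numeric vectors of equal length.
#' @return scalar similarity.
#' @export
embeddingSimilarity <- function(e1, e2) {
  if (length(e1) != length(e2)) stop("embedding dimensions differ")
  1 - log(max(sqrt(sum((e1 - e2)^2)), 1e-8))
}

#' Jaccard index of two sets
#'
#' \code{|intersection| / |union|}; two empty sets score 1 by
#' convention (identical annotation).
#'
#' @param s1,s2 vectors interpreted as sets.
#' @return value in [0, 1].
#' @export
jaccardIndex <- function(s1, s2) {
  s1 <- unique(s1); s2 <- unique(s2)
  if (length(s1) == 0L && length(s2) == 0L) return(1)
  length(intersect(s1, s2)) / length(union(s1, s2))
}

#' Base-pair Jaccard index of two genomic interval sets
#'
#' Intervals are merged within each set; the index is the number of
#' bases covered by both sets divided by the number covered by either,
#' so two fully overlapping interval sets score 1 and the value is
#' invariant to how a covered region is split into intervals. Interval
#' sets on different chromosomes score 0 with a warning.
#'
#' @param ivs1,ivs2 \code{GRanges} (strand is ignored).
#' @return value in [0, 1].
#' @export
intervalJaccard <- function(ivs1, ivs2) {
  if (length(ivs1) == 0L || length(ivs2) == 0L) return(0)
  c1 <- unique(as.character(seqnames(ivs1)))
  c2 <- unique(as.character(seqnames(ivs2)))
  if (length(c1) != 1L || length(c2) != 1L || c1 != c2) {
    warning("interval sets on different chromosomes; Jaccard = 0")
    return(0)
  }
  r1 <- IRanges::reduce(GenomicRanges::ranges(ivs1))
  r2 <- IRanges::reduce(GenomicRanges::ranges(ivs2))
  inter <- sum(IRanges::width(IRanges::intersect(r1, r2)))
  uni <- sum(IRanges::width(IRanges::union(r1, r2)))
  inter / uni
}

# CDS-restricted exon intervals of a coding model.
.cdsRanges <- function(model) {
  ex <- exonRanges(model)
  if (!isCoding(model)) return(ex[0])
  r <- IRanges::restrict(GenomicRanges::ranges(ex),
                         start = as.integer(model@cdsStart),
                         end = as.integer(model@cdsEnd))
  r <- r[IRanges::width(r) > 0L]
  GRanges(as.character(seqnames(ex))[1L], r)
}

#' Sample transcript pair groups for similarity analysis
#'
#' Builds the three comparison groups: \code{intragene} (pairs of
#' protein-coding isoforms within sampled genes), \code{intergene}
#' (canonical transcripts of sampled non-homologous gene pairs) and
#' \code{same_GO} (canonical transcripts of non-homologous gene pairs
#' sharing a functional class). Requested counts scale down when the
#' corpus is smaller than asked for.
#'
#' @param corpus a \code{synthetic_corpus}.
#' @param nIntrageneGenes genes sampled for intragene pairs.
#' @param nIntergene non-homologous gene pairs.
#' @param nGoTerms functional classes sampled.
#' @param pairsPerTerm gene pairs per class.
#' @param seed RNG seed.
#' @return data.frame with \code{id1}, \code{id2}, \code{group},
#'   \code{geneId} (for intragene pairs).
#' @export
samplePairGroups <- function(corpus, nIntrageneGenes = 1000L,
                             nIntergene = 1000L, nGoTerms = 5000L,
                             pairsPerTerm = 5L, seed = 1L) {
  lb <- corpus$labels[corpus$labels$species == "ref", ]
  withr::with_seed(seed, {
    rows <- list()
    byGene <- split(lb$transcriptId, lb$geneId)
    multi <- names(byGene)[lengths(byGene) >= 2L]
    gsel <- sample(multi, min(nIntrageneGenes, length(multi)))
    for (g in gsel) {
      tx <- byGene[[g]]
      cmb <- utils::combn(tx, 2L)
      rows[[paste0("ig_", g)]] <- data.frame(
        id1 = cmb[1L, ], id2 = cmb[2L, ], group = "intragene", geneId = g,
        stringsAsFactors = FALSE)
    }
    canon <- lb[lb$canonical, ]
    famOf <- stats::setNames(canon$familyId, canon$geneId)
    classOf <- stats::setNames(canon$class, canon$geneId)
    txOf <- stats::setNames(canon$transcriptId, canon$geneId)
    genes <- canon$geneId
    nInter <- min(nIntergene, choose(length(genes), 2L))
    got <- 0L; seen <- character()
    interRows <- list()
    while (got < nInter) {
      pr <- sample(genes, 2L)
      key <- paste(sort(pr), collapse = "|")
      if (key %in% seen || famOf[pr[1L]] == famOf[pr[2L]]) next
      seen <- c(seen, key)
      got <- got + 1L
      interRows[[got]] <- data.frame(
        id1 = txOf[pr[1L]], id2 = txOf[pr[2L]], group = "intergene",
        geneId = NA_character_, stringsAsFactors = FALSE)
    }
    rows[["inter"]] <- do.call(rbind, interRows)
    if (!is.null(classOf) && length(unique(classOf)) > 0L) {
      classes <- names(which(table(classOf) >= 2L))
      csel <- if (length(classes))
        sample(classes, min(nGoTerms, length(classes)), replace = FALSE)
      else character()
      goRows <- list()
      for (cl in csel) {
        cg <- names(classOf)[classOf == cl]
        pairsWanted <- min(pairsPerTerm, choose(length(cg), 2L))
        tries <- 0L; made <- 0L; seenC <- character()
        while (made < pairsWanted && tries < 50L * pairsPerTerm) {
          tries <- tries + 1L
          pr <- sample(cg, 2L)
          key <- paste(sort(pr), collapse = "|")
          if (key %in% seenC || famOf[pr[1L]] == famOf[pr[2L]]) next
          seenC <- c(seenC, key)
          made <- made + 1L
          goRows[[paste(cl, made)]] <- data.frame(
            id1 = txOf[pr[1L]], id2 = txOf[pr[2L]], group = "same_GO",
            geneId = NA_character_, stringsAsFactors = FALSE)
        }
      }
      if (length(goRows)) rows[["go"]] <- do.call(rbind, goRows)
    } else {
      warning("corpus has no functional classes; same_GO group skipped")
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Fill a pair table with similarity metrics and group statistics
#'
#' For every pair computes the embedding similarity score, the protein
#' domain Jaccard index (when domain annotations are supplied) and the
#' CDS-overlap and full-sequence-overlap interval Jaccard indices (when
#' transcript models are supplied). Group differences are tested with
#' two-sided Mann-Whitney U tests; for genes with enough intragene
#' pairs, per-gene Pearson and Spearman correlations of the domain
#' Jaccard with the embedding similarity and with two baselines
#' (transcript-length similarity and sequence overlap) are reported.
#'
#' @param pairs data.frame from \code{\link{samplePairGroups}}.
#' @param embeddings matrix with transcript ids as rownames.
#' @param domains optional named list of per-transcript domain id sets.
#' @param models optional named list of \linkS4class{TranscriptModel}.
#' @return list: \code{pairs} (filled table), \code{groupTests}
#'   (pairwise Mann-Whitney results), \code{geneCorrelations}.
#' @export
similarityReport <- function(pairs, embeddings, domains = NULL,
                             models = NULL) {
  have <- pairs$id1 %in% rownames(embeddings) &
    pairs$id2 %in% rownames(embeddings)
  if (any(!have)) {
    message(sum(!have), " pair(s) dropped for missing embeddings")
    pairs <- pairs[have, , drop = FALSE]
  }
  pairs$embeddingScore <- vapply(seq_len(nrow(pairs)), function(i)
    embeddingSimilarity(embeddings[pairs$id1[i], ],
                        embeddings[pairs$id2[i], ]), numeric(1L))
  if (!is.null(domains))
    pairs$domainJaccard <- vapply(seq_len(nrow(pairs)), function(i)
      jaccardIndex(domains[[pairs$id1[i]]] %||% character(),
                   domains[[pairs$id2[i]]] %||% character()), numeric(1L))
  if (!is.null(models)) {
    pairs$cdsJaccard <- vapply(seq_len(nrow(pairs)), function(i) {
      m1 <- models[[pairs$id1[i]]]; m2 <- models[[pairs$id2[i]]]
      if (is.null(m1) || is.null(m2)) return(NA_real_)
      suppressWarnings(intervalJaccard(.cdsRanges(m1), .cdsRanges(m2)))
    }, numeric(1L))
    pairs$sequenceJaccard <- vapply(seq_len(nrow(pairs)), function(i) {
      m1 <- models[[pairs$id1[i]]]; m2 <- models[[pairs$id2[i]]]
      if (is.null(m1) || is.null(m2)) return(NA_real_)
      suppressWarnings(intervalJaccard(exonRanges(m1), exonRanges(m2)))
    }, numeric(1L))
  }
  groups <- unique(pairs$group)
  tests <- list()
  if (length(groups) >= 2L) {
    cmb <- utils::combn(groups, 2L)
    for (k in seq_len(ncol(cmb))) {
      a <- pairs$embeddingScore[pairs$group == cmb[1L, k]]
      b <- pairs$embeddingScore[pairs$group == cmb[2L, k]]
      wt <- stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE)
      tests[[paste(cmb[, k], collapse = "_vs_")]] <- list(
        group1 = cmb[1L, k], group2 = cmb[2L, k],
        median1 = stats::median(a), median2 = stats::median(b),
        p = unname(wt$p.value))
    }
  }
  geneCor <- NULL
  if (!is.null(domains) && !is.null(models)) {
    ig <- pairs[pairs$group == "intragene", , drop = FALSE]
    lenOf <- function(id) sum(width(exonRanges(models[[id]])))
    ig$lengthSimilarity <- vapply(seq_len(nrow(ig)), function(i) {
      l1 <- lenOf(ig$id1[i]); l2 <- lenOf(ig$id2[i])
      min(l1, l2) / max(l1, l2)
    }, numeric(1L))
    rows <- list()
    for (g in unique(ig$geneId)) {
      sub <- ig[ig$geneId == g, ]
      if (nrow(sub) < 3L || stats::sd(sub$domainJaccard) == 0) next
      safeCor <- function(x, y, method)
        if (stats::sd(y) == 0) NA_real_ else
          stats::cor(x, y, method = method)
      rows[[g]] <- data.frame(
        geneId = g, nPairs = nrow(sub),
        pearsonEmbedding = safeCor(sub$domainJaccard,
                                 sub$embeddingScore, "pearson"),
        spearmanEmbedding = safeCor(sub$domainJaccard,
                                  sub$embeddingScore, "spearman"),
        pearsonLength = safeCor(sub$domainJaccard,
                                sub$lengthSimilarity, "pearson"),
        pearsonSeqOverlap = safeCor(sub$domainJaccard,
                                    sub$sequenceJaccard, "pearson"))
    }
    if (length(rows)) {
      geneCor <- do.call(rbind, rows)
      rownames(geneCor) <- NULL
    }
  }
  list(pairs = pairs, groupTests = tests, geneCorrelations = geneCor)
}

#' Cluster the isoforms of one gene by embedding similarity
#'
#' Computes the pairwise embedding-similarity matrix, min-max
#' normalizes it within the gene, and applies average-linkage
#' hierarchical clustering on \code{max - similarity}. Leaf order is
#' deterministic.
#'
#' @param embeddings matrix of the gene's isoform embeddings (>= 2
#'   rows, rownames = transcript ids).
#' @return list: \code{hclust}, \code{order} (leaf ids),
#'   \code{similarity} (normalized matrix), \code{tree} (newick
#'   string).
#' @export
clusterIsoforms <- function(embeddings) {
  n <- nrow(embeddings)
  if (is.null(n) || n < 2L) stop("need at least two isoforms to cluster")
  ids <- rownames(embeddings) %||% paste0("iso", seq_len(n))
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n))
    S[i, j] <- embeddingSimilarity(embeddings[i, ], embeddings[j, ])
  rng <- range(S)
  Sn <- if (diff(rng) > 0) (S - rng[1L]) / diff(rng) else S * 0 + 1
  D <- stats::as.dist(max(Sn) - Sn)
  hc <- stats::hclust(D, method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, order = ids[hc$order], similarity = Sn,
       tree = ape::write.tree(phy))
}

#' Embedding change upon deleting one exon
#'
#' Removes the given exon from the transcript model, recomputes the CDS
#' annotation (a deletion that removes a non-multiple-of-3 stretch of
#' CDS, or a CDS boundary, leaves the transcript flagged frame-broken
#' and treated as non-coding for encoding), re-extracts and re-encodes
#' the mature RNA, and returns the L2 distance between the original and
#' deleted-exon embeddings. \code{exonIndex = 0} is the no-op guard and
#' returns exactly 0.
#'
#' @param model a \linkS4class{TranscriptModel}.
#' @param exonIndex 1-based exon index in genomic order (0 for no-op).
#' @param genome named \code{DNAStringSet}.
#' @param encoder an \linkS4class{RNAEncoder}.
#' @param maxLen encoding length cap.
#' @return the non-negative delta, with attribute \code{frameBroken}.
#' @export
exonDeletionDelta <- function(model, exonIndex, genome, encoder,
                              maxLen = NULL) {
  if (is.null(maxLen)) maxLen <- encoder@config$maxLen
  ex <- exonRanges(model)
  if (exonIndex < 0L || exonIndex > length(ex))
    stop("exonIndex out of range")
  embed1 <- encodeSequence(encoder,
    encodeSixTrack(extractMatureRNA(model, genome), maxLen))$embedding
  if (exonIndex == 0L) {
    out <- 0
    attr(out, "frameBroken") <- FALSE
    return(out)
  }
  if (length(ex) == 1L) stop("cannot delete the only exon")
  keep <- ex[-exonIndex]
  frameBroken <- FALSE
  cs <- model@cdsStart; ce <- model@cdsEnd
  if (isCoding(model)) {
    dEx <- ex[exonIndex]
    lost <- .exonOverlapLen(dEx, cs, ce)
    boundaryHit <- (cs >= start(dEx) && cs <= end(dEx)) ||
      (ce >= start(dEx) && ce <= end(dEx))
    if (boundaryHit || lost %% 3L != 0L) {
      frameBroken <- TRUE
      cs <- NA_real_; ce <- NA_real_
    }
  }
  m2 <- TranscriptModel(
    transcriptId = paste0(transcriptId(model), "_del", exonIndex),
    geneId = geneId(model), geneName = geneName(model),
    species = speciesId(model), exons = keep,
    cdsStart = cs, cdsEnd = ce, biotype = model@biotype)
  embed2 <- encodeSequence(encoder,
    encodeSixTrack(extractMatureRNA(m2, genome), maxLen))$embedding
  out <- sqrt(sum((embed1 - embed2)^2))
  attr(out, "frameBroken") <- frameBroken
  out
}
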