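#' Build splicing augmentation sets
#'
#' Groups transcripts by gene: every other isoform of a transcript's
#' gene becomes a member of its positive-sample set with source
#' \code{splicing}. Single-isoform genes yield empty sets (such
#' references later fall back to the masking augmentation when a pair
#' is sampled).
#'
#' @param models list of \linkS4class{TranscriptModel}.
#' @return an \linkS4class{AugmentationSets}.
#' @export
buildSplicingSets <- function(models) {
  ids <- unname(vapply(models, transcriptId, character(1L)))
  genes <- unname(vapply(models, geneId, character(1L)))
  rows <- list()
  for (g in unique(genes)) {
    member <- ids[genes == g]
    if (length(member) > 1L) {
      grid <- expand.grid(referenceId = member, memberId = member,
                          stringsAsFactors = FALSE)
      grid <- grid[grid$referenceId != grid$memberId, ]
      rows[[g]] <- grid
    }
  }
  p <- if (length(rows)) do.call(rbind, rows) else
    data.frame(referenceId = character(), memberId = character())
  p$source <- rep("splicing", nrow(p))
  p$cdsOnly <- rep(FALSE, nrow(p))
  rownames(p) <- NULL
  new("AugmentationSets", pairs = p, referenceIds = unname(ids))
}

#' Append orthology members to augmentation sets
#'
#' @param sets an \linkS4class{AugmentationSets} built over the
#'   reference species.
#' @param mapping data.frame with columns \code{referenceId} and
#'   \code{orthologId} linking reference transcripts to ortholog
#'   transcript ids (TOGA-style projections).
#' @param orthologModels list of \linkS4class{TranscriptModel} for the
#'   orthologs; orthologs whose CDS spans the whole transcript (no
#'   UTRs) are flagged \code{cdsOnly} so that pair sampling can apply
#'   the chimeric UTR transform.
#' @param orthologRnas optional named list of \linkS4class{MatureRNA}
#'   for the orthologs, used for the UTR check when models alone are
#'   ambiguous.
#' @return the updated \linkS4class{AugmentationSets}.
#' @export
buildOrthologySets <- function(sets, mapping, orthologModels,
                               orthologRnas = NULL) {
  if (nrow(mapping) == 0L) return(sets)
  oids <- vapply(orthologModels, transcriptId, character(1L))
  known <- mapping$orthologId %in% oids
  if (any(!known)) {
    warning(sum(!known), " mapping entr(ies) point to unknown ortholog ids; skipped")
    mapping <- mapping[known, , drop = FALSE]
  }
  knownRef <- mapping$referenceId %in% sets@referenceIds
  if (any(!knownRef)) {
    warning(sum(!knownRef), " mapping entr(ies) have unknown reference ids; skipped")
    mapping <- mapping[knownRef, , drop = FALSE]
  }
  if (nrow(mapping) == 0L) return(sets)
  cdsOnly <- vapply(mapping$orthologId, function(id) {
    if (!is.null(orthologRnas) && id %in% names(orthologRnas)) {
      sl <- segmentLengths(orthologRnas[[id]])
      return(sl[["utr5"]] == 0L && sl[["utr3"]] == 0L && sl[["cds"]] > 0L)
    }
    m <- orthologModels[[match(id, oids)]]
    if (!isCoding(m)) return(FALSE)
    ex <- exonRanges(m)
    m@cdsStart <= min(start(ex)) && m@cdsEnd >= max(end(ex))
  }, logical(1L))
  add <- data.frame(referenceId = mapping$referenceId,
                    memberId = mapping$orthologId,
                    source = "orthology", cdsOnly = cdsOnly,
                    stringsAsFactors = FALSE)
  p <- unique(rbind(sets@pairs, add))
  rownames(p) <- NULL
  new("AugmentationSets", pairs = p, referenceIds = sets@referenceIds)
}

#' Merge naive orthology into augmentation sets
#'
#' Naive orthology pools transcripts across species purely by gene
#' identity: for every reference transcript, transcripts of genes with
#' exactly the same (case-sensitive) name in \emph{other} species are
#' appended with source \code{naive_orthology}. Homonym collisions are
#' accepted.
#'
#' @param sets an \linkS4class{AugmentationSets}.
#' @param models list of \linkS4class{TranscriptModel} across species
#'   (including the reference species).
#' @return the updated \linkS4class{AugmentationSets}.
#' @export
mergeNaiveOrthology <- function(sets, models) {
  ids <- unname(vapply(models, transcriptId, character(1L)))
  nm <- unname(vapply(models, geneName, character(1L)))
  sp <- unname(vapply(models, speciesId, character(1L)))
  refIdx <- match(sets@referenceIds, ids)
  rows <- list()
  for (k in seq_along(sets@referenceIds)) {
    i <- refIdx[k]
    if (is.na(i)) next
    hit <- which(nm == nm[i] & sp != sp[i])
    if (length(hit))
      rows[[k]] <- data.frame(referenceId = ids[i], memberId = ids[hit],
                              source = "naive_orthology", cdsOnly = FALSE,
                              stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(sets)
  p <- unique(rbind(sets@pairs, do.call(rbind, rows)))
  rownames(p) <- NULL
  new("AugmentationSets", pairs = p, referenceIds = sets@referenceIds)
}

#' Chimeric UTR combination transform
#'
#' Zoonomia-style orthologs lack UTRs; to stop the contrastive
#' objective from discounting UTRs, an orthology-sourced positive is
#' turned into a chimera: the reference isoform's 5'UTR, the ortholog's
#' coding sequence, and the reference isoform's 3'UTR. Codon starts are
#' recomputed for the ortholog CDS at its new offset, the ortholog's
#' CDS junctions are preserved with shifted coordinates, and the
#' isoform's own UTR junctions are kept (shifted for the 3'UTR).
#'
#' @param isoform a coding \linkS4class{MatureRNA} supplying the UTRs.
#' @param orthologCds a \linkS4class{MatureRNA} that is all CDS.
#' @return the chimeric \linkS4class{MatureRNA}.
#' @export
utrCombinationTransform <- function(isoform, orthologCds) {
  sl <- segmentLengths(isoform)
  if (sl[["cds"]] == 0L) stop("isoform must be coding for the UTR transform")
  osl <- segmentLengths(orthologCds)
  if (osl[["cds"]] != length(orthologCds))
    stop("orthologCds must be coding over its full length")
  u5 <- sl[["utr5"]]; u3 <- sl[["utr3"]]
  isoSeq <- rnaSequence(isoform)
  L <- nchar(isoSeq)
  utr5seq <- substr(isoSeq, 1L, u5)
  utr3seq <- substr(isoSeq, L - u3 + 1L, L)
  cdsSeq <- rnaSequence(orthologCds)
  cdsLen <- nchar(cdsSeq)
  isoJ <- junctions(isoform)
  j5 <- isoJ[isoJ > 0L & isoJ < u5]
  jCds <- junctions(orthologCds) + u5
  shift3 <- u5 + cdsLen - (u5 + sl[["cds"]])
  j3 <- isoJ[isoJ > u5 + sl[["cds"]] & isoJ < L] + shift3
  # junctions landing exactly on segment boundaries are kept once
  jB <- c(if (u5 %in% isoJ || any(junctions(orthologCds) == 0L)) u5,
          if ((u5 + sl[["cds"]]) %in% isoJ) u5 + cdsLen)
  codon <- u5 + 3L * (seq_len(cdsLen %/% 3L) - 1L)
  new("MatureRNA",
      transcriptId = paste0(transcriptId(isoform), "|",
                            transcriptId(orthologCds), "|chimera"),
      sequence = DNAString(paste0(utr5seq, cdsSeq, utr3seq)),
      junctions = sort(unique(as.integer(c(j5, jCds, j3, jB)))),
      codonStarts = as.integer(codon),
      utr5Len = as.integer(u5), cdsLen = as.integer(cdsLen),
      utr3Len = as.integer(u3))
}

#' Masking augmentation
#'
#' Zeroes the nucleotide tracks at \code{floor(fraction * L)} uniformly
#' chosen valid positions (default 30\%); the splice-junction and
#' codon-start tracks are untouched and the input is not modified in
#' place. Serves as the fallback augmentation for references with empty
#' positive-sample sets.
#'
#' @param enc a \linkS4class{SixTrackEncoding}.
#' @param fraction masked fraction in [0, 1].
#' @param seed RNG seed.
#' @return the masked \linkS4class{SixTrackEncoding}.
#' @export
maskAugment <- function(enc, fraction = 0.30, seed = 1L) {
  .maskPositions(enc, fraction, seed)$enc
}

# Deterministic 31-bit string hash (seed, epoch, id) -> integer; keeps
# epoch resampling reproducible without storing draws.
.stableHash <- function(...) {
  s <- paste(..., sep = "\r")
  b <- utf8ToInt(s)
  h <- 0
  for (v in b) h <- (h * 31 + v) %% 2147483629
  as.integer(h)
}

#' Sample a positive pair for one reference transcript
#'
#' Draws a member uniformly from the union of all augmentation sources
#' for the reference. Orthology draws of CDS-only members pass through
#' \code{\link{utrCombinationTransform}} with the reference's UTRs. A
#' reference with an empty set falls back to the masking augmentation
#' (reference paired with its 30\%-masked self). The draw is
#' deterministic given \code{(seed, epoch, referenceId)}, and
#' re-sampling across epochs changes the drawn member.
#'
#' @param referenceId reference transcript id.
#' @param sets an \linkS4class{AugmentationSets}.
#' @param rnas named list of \linkS4class{MatureRNA} covering the
#'   reference and all members.
#' @param epoch training epoch (part of the sampling key).
#' @param seed base RNG seed.
#' @param orthologyWeight positive-pair weight for orthology draws
#'   (default 0.8).
#' @param maskFraction masking fraction for masking-sourced pairs and
#'   the empty-set fallback.
#' @param maxLen encoding length cap.
#' @param includeMasking if TRUE the 30\%-masked reference participates
#'   in the union of augmentation sources as one additional member
#'   (the masking augmentation of the full four-source scheme); if
#'   FALSE masking is used only as the empty-set fallback.
#' @return list of class \code{positive_pair}: \code{x1}, \code{x2}
#'   (\linkS4class{SixTrackEncoding}), \code{source}, \code{weight},
#'   \code{memberId}.
#' @export
samplePositivePair <- function(referenceId, sets, rnas, epoch = 1L,
                               seed = 1L, orthologyWeight = 0.8,
                               maskFraction = 0.30, maxLen = 12288L,
                               includeMasking = FALSE) {
  members <- setMembers(sets, referenceId)
  refRna <- rnas[[referenceId]]
  if (is.null(refRna)) stop("no mature RNA for reference ", referenceId)
  h <- .stableHash(seed, epoch, referenceId)
  x1 <- encodeSixTrack(refRna, maxLen)
  nUnion <- nrow(members) + as.integer(isTRUE(includeMasking))
  if (nUnion == 0L || (h %% nUnion) + 1L > nrow(members)) {
    x2 <- maskAugment(x1, maskFraction, seed = h)
    out <- list(x1 = x1, x2 = x2, source = "masking", weight = 1.0,
                memberId = referenceId)
    class(out) <- "positive_pair"
    return(out)
  }
  k <- (h %% nUnion) + 1L
  pick <- members[k, ]
  memRna <- rnas[[pick$memberId]]
  if (is.null(memRna)) stop("no mature RNA for member ", pick$memberId)
  if (pick$source == "orthology" && pick$cdsOnly &&
      segmentLengths(refRna)[["cds"]] > 0L)
    memRna <- utrCombinationTransform(refRna, memRna)
  x2 <- encodeSixTrack(memRna, maxLen)
  w <- if (pick$source == "orthology") orthologyWeight else 1.0
  out <- list(x1 = x1, x2 = x2, source = pick$source, weight = w,
              memberId = pick$memberId)
  class(out) <- "positive_pair"
  out
}

#' Count contrastive pairs
#'
#' Ordered reference-to-member pairs, total and per source.
#'
#' @param sets an \linkS4class{AugmentationSets}.
#' @return a \code{pair_stats} list: \code{n_transcripts},
#'   \code{n_pairs}, \code{perSource}.
#' @export
countPairs <- function(sets) {
  tab <- table(factor(sets@pairs$source,
                      levels = c("splicing", "orthology", "naive_orthology")))
  out <- list(n_transcripts = length(sets@referenceIds),
              n_pairs = nrow(sets@pairs),
              perSource = as.list(as.integer(tab)))
  names(out$perSource) <- names(tab)
  class(out) <- "pair_stats"
  out
}

#' @export
print.pair_stats <- function(x, ...) {
  cat(sprintf("%d transcripts, %d ordered positive pairs\n",
              x$n_transcripts, x$n_pairs))
  for (s in names(x$perSource))
    cat(sprintf("  %s: %d\n", s, x$perSource[[s]]))
  invisible(x)
}

#' Write a pair manifest TSV
#'
#' @param sets an \linkS4class{AugmentationSets}.
#' @param path output TSV path.
#' @param orthologyWeight weight recorded for orthology rows.
#' @return invisibly, the path.
#' @export
writePairManifest <- function(sets, path, orthologyWeight = 0.8) {
  p <- sets@pairs
  p$weight <- ifelse(p$source == "orthology", orthologyWeight, 1.0)
  utils::write.table(p[, c("referenceId", "memberId", "source", "weight")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
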