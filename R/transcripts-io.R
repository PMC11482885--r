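#' Read a UCSC genePred annotation file
#'
#' Parses tab-separated genePred rows (GENCODE/RefSeq dialects) into
#' \linkS4class{TranscriptModel} objects. A leading UCSC \code{bin}
#' column is auto-detected. genePred coordinates are 0-based half-open
#' and are converted to the 1-based closed convention used internally.
#' \code{cdsStart == cdsEnd} denotes a non-coding transcript. When the
#' extended dialect carries a \code{name2} column it is used as the gene
#' name; otherwise the transcript name doubles as gene id.
#'
#' Rows whose exon arrays disagree with \code{exonCount} raise an error
#' naming the offending line; rows with malformed coordinates (negative
#' or inverted intervals) are reported and skipped.
#'
#' @param path path to a genePred file.
#' @param species species tag recorded on each model.
#' @return a named list of \linkS4class{TranscriptModel} objects.
#' @export
readGenePred <- function(path, species = "ref") {
  if (!file.exists(path)) stop("cannot read genePred file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- vector("list", length(lines))
  keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    # bin column: first field numeric and second non-numeric (the name)
    if (length(f) >= 11L && !is.na(suppressWarnings(as.numeric(f[1L]))) &&
        is.na(suppressWarnings(as.numeric(f[2L]))))
      f <- f[-1L]
    if (length(f) < 10L)
      stop("genePred parse error at line ", i, ": expected >= 10 fields")
    name <- f[1L]; chrom <- f[2L]; strand <- f[3L]
    txStart <- as.numeric(f[4L]); txEnd <- as.numeric(f[5L])
    cdsStart0 <- as.numeric(f[6L]); cdsEnd0 <- as.numeric(f[7L])
    exonCount <- as.integer(f[8L])
    starts <- as.numeric(strsplit(sub(",$", "", f[9L]), ",")[[1L]])
    ends <- as.numeric(strsplit(sub(",$", "", f[10L]), ",")[[1L]])
    if (length(starts) != exonCount || length(ends) != exonCount)
      stop("genePred parse error at line ", i,
           ": exonStarts/exonEnds length does not match exonCount")
    geneName <- if (length(f) >= 12L && nzchar(f[12L])) f[12L] else name
    if (anyNA(c(txStart, txEnd, cdsStart0, cdsEnd0, starts, ends)) ||
        any(ends <= starts) || any(starts < 0)) {
      warning("skipping genePred line ", i, " (malformed coordinates)")
      next
    }
    coding <- cdsEnd0 > cdsStart0
    out[[i]] <- TranscriptModel(
      transcriptId = name, geneId = geneName, geneName = geneName,
      species = species,
      exons = GRanges(chrom, IRanges(starts + 1, ends), strand = strand),
      cdsStart = if (coding) cdsStart0 + 1 else NA_real_,
      cdsEnd = if (coding) cdsEnd0 else NA_real_)
    keep[i] <- TRUE
  }
  out <- out[keep]
  names(out) <- vapply(out, transcriptId, character(1L))
  out
}

#' Read a BED12 annotation file (TOGA-style ortholog projections)
#'
#' Uses \code{\link[rtracklayer]{import}} to parse BED12; exon blocks
#' become the model's exons and the thick interval becomes the CDS
#' (\code{thickStart == thickEnd} denotes non-coding, per BED
#' convention). The BED name field is taken as transcript id; a
#' \code{"gene.transcript"} dotted name contributes the gene part.
#'
#' @inheritParams readGenePred
#' @return a named list of \linkS4class{TranscriptModel} objects.
#' @export
readTogaBed <- function(path, species = "ortho") {
  if (!file.exists(path)) stop("cannot read BED file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("BED12 parse error in ", path,
                                          ": ", conditionMessage(e)))
  blocks <- rtracklayer::blocks(gr)
  out <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    nm <- gr$name[i]
    gene <- sub("\\..*$", "", nm)
    thick <- gr$thick[i]
    coding <- IRanges::width(thick) > 0L
    ex <- blocks[[i]]
    GenomicRanges::strand(ex) <- as.character(strand(gr))[i]
    out[[i]] <- TranscriptModel(
      transcriptId = nm, geneId = gene, geneName = gene, species = species,
      exons = ex,
      cdsStart = if (coding) start(thick) else NA_real_,
      cdsEnd = if (coding) end(thick) else NA_real_)
  }
  names(out) <- vapply(out, transcriptId, character(1L))
  out
}

# Mature-coordinate length of the overlap between the exon set and a
# genomic interval (1-based closed).
.exonOverlapLen <- function(exons, lo, hi) {
  if (hi < lo) return(0L)
  s <- pmax(start(exons), lo); e <- pmin(end(exons), hi)
  sum(pmax(0L, e - s + 1L))
}

#' Extract the mature RNA of a transcript
#'
#' Concatenates exon sequences in 5' to 3' transcript order
#' (reverse-complementing minus-strand transcripts), and derives
#' splice-junction and codon-start positions in 0-based mature
#' coordinates. The stop codon is counted inside the CDS.
#'
#' @param model a \linkS4class{TranscriptModel}.
#' @param genome a named \code{DNAStringSet} (chromosome sequences).
#' @return a \linkS4class{MatureRNA}.
#' @export
extractMatureRNA <- function(model, genome) {
  ex <- exonRanges(model)
  chrom <- as.character(seqnames(ex))[1L]
  if (!chrom %in% names(genome))
    stop("chromosome not found in genome: ", chrom)
  chromSeq <- genome[[chrom]]
  if (max(end(ex)) > length(chromSeq))
    stop("exon beyond chromosome end on ", chrom)
  minus <- as.character(strand(ex))[1L] == "-"
  pieces <- lapply(seq_along(ex), function(i)
    Biostrings::subseq(chromSeq, start(ex)[i], end(ex)[i]))
  seq <- do.call(Biostrings::xscat, pieces)
  if (minus) seq <- reverseComplement(seq)
  w <- width(ex)
  if (minus) w <- rev(w)
  junc <- if (length(w) > 1L) cumsum(w)[-length(w)] else integer()
  L <- sum(w)
  if (isCoding(model)) {
    cs <- model@cdsStart; ce <- model@cdsEnd
    cdsLen <- .exonOverlapLen(ex, cs, ce)
    utr5 <- if (minus) .exonOverlapLen(ex, ce + 1L, max(end(ex)))
            else       .exonOverlapLen(ex, min(start(ex)), cs - 1L)
    utr3 <- L - utr5 - cdsLen
    if (cdsLen %% 3L != 0L)
      stop("CDS length not divisible by 3 for ", transcriptId(model))
    codon <- utr5 + 3L * (seq_len(cdsLen %/% 3L) - 1L)
  } else {
    utr5 <- 0L; cdsLen <- 0L; utr3 <- L; codon <- integer()
  }
  seqChr <- toupper(as.character(seq))
  new("MatureRNA", transcriptId = transcriptId(model),
      sequence = DNAString(seqChr),
      junctions = as.integer(junc), codonStarts = as.integer(codon),
      utr5Len = as.integer(utr5), cdsLen = as.integer(cdsLen),
      utr3Len = as.integer(utr3))
}

.NUC <- c("A", "C", "G", "T")

#' Encode a mature RNA as a six-track matrix
#'
#' Columns 1-4 one-hot the nucleotide (fixed order A, C, G, T; N rows
#' are all zero), column 5 marks splice junctions and column 6 marks
#' codon starts. Sequences longer than \code{maxLen} are truncated by
#' dropping the 3' end, which preserves the 5'UTR and CDS start.
#'
#' @param rna a \linkS4class{MatureRNA}.
#' @param maxLen maximum encoded length (default 12288, the longest
#'   mature mRNA length the encoder is configured for).
#' @return a \linkS4class{SixTrackEncoding}.
#' @export
encodeSixTrack <- function(rna, maxLen = 12288L) {
  stopifnot(maxLen >= 1L)
  s <- strsplit(rnaSequence(rna), "")[[1L]]
  if (length(s) == 0L) stop("cannot encode an empty sequence")
  L <- min(length(s), maxLen)
  s <- s[seq_len(L)]
  m <- matrix(0, nrow = L, ncol = 6L)
  for (k in 1:4) m[s == .NUC[k], k] <- 1
  j <- junctions(rna); j <- j[j < L]
  m[j + 1L, 5L] <- 1
  cs <- codonStarts(rna); cs <- cs[cs < L]
  m[cs + 1L, 6L] <- 1
  new("SixTrackEncoding", mat = m, mask = rep(TRUE, L))
}

#' Decode a six-track encoding back to a MatureRNA
#'
#' Inverse of \code{\link{encodeSixTrack}} for sequences within the
#' encoder's maximum length: all-zero nucleotide rows decode to
#' \code{N}; segment lengths are reconstructed from the codon-start
#' track (contiguous codons spanning the CDS).
#'
#' @param enc a \linkS4class{SixTrackEncoding}.
#' @return a \linkS4class{MatureRNA}.
#' @export
decodeSixTrack <- function(enc) {
  m <- trackMatrix(enc)[validMask(enc), , drop = FALSE]
  if (any(rowSums(m[, 1:4, drop = FALSE]) > 1))
    stop("invalid encoding: two nucleotide tracks set at one position")
  L <- nrow(m)
  idx <- m[, 1:4, drop = FALSE] %*% (1:4)
  s <- rep("N", L)
  hit <- idx > 0
  s[hit] <- .NUC[idx[hit]]
  junc <- which(m[, 5L] == 1) - 1L
  codon <- which(m[, 6L] == 1) - 1L
  if (length(codon)) {
    utr5 <- min(codon); cdsLen <- 3L * length(codon)
    utr3 <- L - utr5 - cdsLen
  } else { utr5 <- 0L; cdsLen <- 0L; utr3 <- L }
  new("MatureRNA", transcriptId = "decoded",
      sequence = DNAString(paste(s, collapse = "")),
      junctions = as.integer(junc), codonStarts = as.integer(codon),
      utr5Len = as.integer(utr5), cdsLen = as.integer(cdsLen),
      utr3Len = as.integer(utr3))
}

#' Write mature RNA sequences as FASTA
#'
#' @param rnas list of \linkS4class{MatureRNA}.
#' @param path output FASTA path.
#' @return invisibly, the path.
#' @export
writeMatureFasta <- function(rnas, path) {
  ss <- DNAStringSet(vapply(rnas, rnaSequence, character(1L)))
  names(ss) <- vapply(rnas, transcriptId, character(1L))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
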