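#' @import methods
#' @importFrom GenomicRanges GRanges start end strand seqnames width
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

#' Transcript gene model
#'
#' Genomic exon/CDS structure of one transcript. Exons are stored as a
#' \link[GenomicRanges]{GRanges} in the usual Bioconductor 1-based closed
#' convention, sorted in ascending genomic coordinate and non-overlapping;
#' all input readers convert from their native coordinate systems
#' (genePred and BED12 are 0-based half-open). \code{cdsStart}/\code{cdsEnd}
#' are 1-based closed genomic coordinates of the coding region, or
#' \code{NA} for non-coding transcripts.
#'
#' @slot transcriptId character(1) transcript identifier.
#' @slot geneId character(1) gene identifier.
#' @slot geneName character(1) gene symbol (used for naive orthology).
#' @slot species character(1) species tag.
#' @slot exons \code{GRanges} of exons, ascending, non-overlapping,
#'   single chromosome and strand.
#' @slot cdsStart,cdsEnd numeric(1) genomic CDS bounds (1-based closed)
#'   or \code{NA_real_} when non-coding.
#' @slot biotype character(1) free-form biotype tag.
#' @export
setClass("TranscriptModel",
  representation(
    transcriptId = "character",
    geneId       = "character",
    geneName     = "character",
    species      = "character",
    exons        = "GRanges",
    cdsStart     = "numeric",
    cdsEnd       = "numeric",
    biotype      = "character"
  )
)

setValidity("TranscriptModel", function(object) {
  ex <- object@exons
  if (length(ex) < 1L) return("transcript must have at least one exon")
  if (length(unique(as.character(seqnames(ex)))) != 1L)
    return("exons must lie on a single chromosome")
  st <- unique(as.character(strand(ex)))
  if (length(st) != 1L || !st %in% c("+", "-"))
    return("exons must share one strand, '+' or '-'")
  s <- start(ex); e <- end(ex)
  if (any(e < s)) return("malformed exon interval")
  if (is.unsorted(s, strictly = TRUE) && length(ex) > 1L)
    return("exons must be sorted in ascending genomic coordinate")
  if (length(ex) > 1L && any(s[-1L] <= e[-length(ex)]))
    return("exons must be non-overlapping")
  cs <- object@cdsStart; ce <- object@cdsEnd
  if (is.na(cs) != is.na(ce))
    return("cdsStart and cdsEnd must both be present or both absent")
  if (!is.na(cs)) {
    if (ce < cs) return("cdsEnd must be >= cdsStart")
    inEx <- any(s <= cs & cs <= e) && any(s <= ce & ce <= e)
    if (!inEx) return("CDS bounds must fall inside the exon union")
  }
  TRUE
})

#' Construct a TranscriptModel
#'
#' @param transcriptId,geneId,geneName,species,biotype identifiers.
#' @param exons a \code{GRanges} of exons (1-based closed).
#' @param cdsStart,cdsEnd genomic CDS bounds (1-based closed) or \code{NA}.
#' @return a \linkS4class{TranscriptModel}.
#' @export
TranscriptModel <- function(transcriptId, geneId, geneName = geneId,
                            species = "ref", exons,
                            cdsStart = NA_real_, cdsEnd = NA_real_,
                            biotype = "protein_coding") {
  o <- GenomicRanges::sort(exons)
  new("TranscriptModel",
      transcriptId = as.character(transcriptId),
      geneId = as.character(geneId),
      geneName = as.character(geneName),
      species = as.character(species),
      exons = o,
      cdsStart = as.numeric(cdsStart), cdsEnd = as.numeric(cdsEnd),
      biotype = as.character(biotype))
}

#' @rdname TranscriptModel-accessors
#' @param x a \linkS4class{TranscriptModel}.
#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))
#' @rdname TranscriptModel-accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname TranscriptModel-accessors
#' @export
setGeneric("geneName", function(x) standardGeneric("geneName"))
#' @rdname TranscriptModel-accessors
#' @export
setGeneric("speciesId", function(x) standardGeneric("speciesId"))
#' @rdname TranscriptModel-accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @rdname TranscriptModel-accessors
#' @export
setGeneric("isCoding", function(x) standardGeneric("isCoding"))

#' Accessors for TranscriptModel
#'
#' @name TranscriptModel-accessors
#' @aliases transcriptId geneId geneName speciesId exonRanges isCoding
NULL

#' @rdname TranscriptModel-accessors
setMethod("transcriptId", "TranscriptModel", function(x) x@transcriptId)
#' @rdname TranscriptModel-accessors
setMethod("geneId", "TranscriptModel", function(x) x@geneId)
#' @rdname TranscriptModel-accessors
setMethod("geneName", "TranscriptModel", function(x) x@geneName)
#' @rdname TranscriptModel-accessors
setMethod("speciesId", "TranscriptModel", function(x) x@species)
#' @rdname TranscriptModel-accessors
setMethod("exonRanges", "TranscriptModel", function(x) x@exons)
#' @rdname TranscriptModel-accessors
setMethod("isCoding", "TranscriptModel", function(x) !is.na(x@cdsStart))

setMethod("show", "TranscriptModel", function(object) {
  cds <- if (isCoding(object))
    sprintf("CDS %d-%d", as.integer(object@cdsStart), as.integer(object@cdsEnd))
  else "non-coding"
  cat(sprintf("TranscriptModel %s (gene %s, %s, %s)\n  %d exon(s) on %s:%s, %s\n",
              object@transcriptId, object@geneId, object@geneName,
              object@species, length(object@exons),
              as.character(seqnames(object@exons))[1L],
              as.character(strand(object@exons))[1L], cds))
})

#' Mature (spliced) RNA
#'
#' The exon-concatenated transcript sequence in 5' to 3' orientation,
#' together with splice-junction and codon-start annotations in
#' 0-based mature-transcript coordinates. The DNA alphabet is used
#' (T, not U). Junctions mark the first nucleotide of each exon after
#' the first; codon starts mark the first nucleotide of every codon of
#' the CDS (the stop codon is counted inside the CDS).
#'
#' @slot transcriptId character(1).
#' @slot sequence \code{DNAString}.
#' @slot junctions integer vector of 0-based mature positions.
#' @slot codonStarts integer vector of 0-based mature positions.
#' @slot utr5Len,cdsLen,utr3Len integer(1), summing to the length.
#' @export
setClass("MatureRNA",
  representation(
    transcriptId = "character",
    sequence     = "DNAString",
    junctions    = "integer",
    codonStarts  = "integer",
    utr5Len      = "integer",
    cdsLen       = "integer",
    utr3Len      = "integer"
  )
)

setValidity("MatureRNA", function(object) {
  L <- length(object@sequence)
  if (L < 1L) return("empty sequence")
  if (object@utr5Len + object@cdsLen + object@utr3Len != L)
    return("utr5Len + cdsLen + utr3Len must equal sequence length")
  if (object@cdsLen > 0L && object@cdsLen %% 3L != 0L)
    return("cdsLen must be divisible by 3 for coding transcripts")
  if (length(object@junctions) &&
      (min(object@junctions) < 1L || max(object@junctions) > L - 1L))
    return("junction positions out of range")
  if (length(object@codonStarts) &&
      (min(object@codonStarts) < 0L || max(object@codonStarts) > L - 1L))
    return("codon-start positions out of range")
  if (!all(grepl("^[ACGTN]*$", as.character(object@sequence))))
    return("sequence must be over {A,C,G,T,N}")
  TRUE
})

#' Construct a MatureRNA
#'
#' @param transcriptId identifier.
#' @param sequence character or \code{DNAString} (case-folded to upper).
#' @param junctions,codonStarts integer vectors, 0-based mature coordinates.
#' @param utr5Len,cdsLen,utr3Len segment lengths; must sum to the length.
#' @return a \linkS4class{MatureRNA}.
#' @export
MatureRNA <- function(transcriptId, sequence, junctions = integer(),
                      codonStarts = integer(), utr5Len = NA, cdsLen = NA,
                      utr3Len = NA) {
  s <- DNAString(toupper(as.character(sequence)))
  L <- length(s)
  if (is.na(cdsLen)) { utr5Len <- 0L; cdsLen <- 0L; utr3Len <- L }
  new("MatureRNA", transcriptId = as.character(transcriptId), sequence = s,
      junctions = sort(as.integer(junctions)),
      codonStarts = sort(as.integer(codonStarts)),
      utr5Len = as.integer(utr5Len), cdsLen = as.integer(cdsLen),
      utr3Len = as.integer(utr3Len))
}

#' @rdname MatureRNA-accessors
#' @param x a \linkS4class{MatureRNA}.
#' @export
setGeneric("rnaSequence", function(x) standardGeneric("rnaSequence"))
#' @rdname MatureRNA-accessors
#' @export
setGeneric("junctions", function(x) standardGeneric("junctions"))
#' @rdname MatureRNA-accessors
#' @export
setGeneric("codonStarts", function(x) standardGeneric("codonStarts"))
#' @rdname MatureRNA-accessors
#' @export
setGeneric("segmentLengths", function(x) standardGeneric("segmentLengths"))

#' Accessors for MatureRNA
#'
#' \code{rnaSequence} returns the sequence as a character scalar;
#' \code{segmentLengths} returns \code{c(utr5, cds, utr3)}.
#'
#' @name MatureRNA-accessors
#' @aliases rnaSequence junctions codonStarts segmentLengths
NULL

#' @rdname MatureRNA-accessors
setMethod("rnaSequence", "MatureRNA", function(x) as.character(x@sequence))
#' @rdname MatureRNA-accessors
setMethod("junctions", "MatureRNA", function(x) x@junctions)
#' @rdname MatureRNA-accessors
setMethod("codonStarts", "MatureRNA", function(x) x@codonStarts)
#' @rdname MatureRNA-accessors
setMethod("segmentLengths", "MatureRNA", function(x)
  c(utr5 = x@utr5Len, cds = x@cdsLen, utr3 = x@utr3Len))
#' @rdname MatureRNA-accessors
setMethod("length", "MatureRNA", function(x) length(x@sequence))
#' @rdname MatureRNA-accessors
setMethod("transcriptId", "MatureRNA", function(x) x@transcriptId)

setMethod("show", "MatureRNA", function(object) {
  cat(sprintf("MatureRNA %s: %d nt (5'UTR %d | CDS %d | 3'UTR %d), %d junction(s)\n",
              object@transcriptId, length(object@sequence), object@utr5Len,
              object@cdsLen, object@utr3Len, length(object@junctions)))
})

#' Six-track encoding of a mature RNA
#'
#' An L x 6 binary matrix: columns 1-4 are the one-hot nucleotide tracks
#' in fixed order A, C, G, T (all zero for N or masked positions), column
#' 5 marks splice junctions (the first nucleotide of each exon after the
#' first) and column 6 marks the first nucleotide of every codon in the
#' CDS. \code{mask} flags valid (non-padding) positions.
#'
#' @slot mat numeric L x 6 matrix over \{0, 1\}.
#' @slot mask logical vector of length L.
#' @export
setClass("SixTrackEncoding",
  representation(mat = "matrix", mask = "logical"))

setValidity("SixTrackEncoding", function(object) {
  m <- object@mat
  if (ncol(m) != 6L) return("matrix must have 6 columns")
  if (nrow(m) != length(object@mask)) return("mask length must match rows")
  if (!all(m %in% c(0, 1))) return("tracks must be binary")
  if (any(rowSums(m[, 1:4, drop = FALSE]) > 1))
    return("nucleotide tracks must sum to <= 1 per position")
  TRUE
})

#' @rdname SixTrackEncoding-accessors
#' @param x a \linkS4class{SixTrackEncoding}.
#' @export
setGeneric("trackMatrix", function(x) standardGeneric("trackMatrix"))
#' @rdname SixTrackEncoding-accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' Accessors for SixTrackEncoding
#' @name SixTrackEncoding-accessors
#' @aliases trackMatrix validMask
NULL

#' @rdname SixTrackEncoding-accessors
setMethod("trackMatrix", "SixTrackEncoding", function(x) x@mat)
#' @rdname SixTrackEncoding-accessors
setMethod("validMask", "SixTrackEncoding", function(x) x@mask)
#' @rdname SixTrackEncoding-accessors
setMethod("length", "SixTrackEncoding", function(x) nrow(x@mat))

setMethod("show", "SixTrackEncoding", function(object) {
  cat(sprintf("SixTrackEncoding: %d positions (%d valid), %d junction(s), %d codon start(s)\n",
              nrow(object@mat), sum(object@mask), sum(object@mat[, 5L]),
              sum(object@mat[, 6L])))
})

#' Augmentation sets for contrastive pair construction
#'
#' The positive-sample sets: for each reference transcript, the related
#' transcripts reachable through alternative splicing, orthology or naive
#' (gene-name) orthology. Stored as one long table of ordered
#' (reference, member, source) rows; \code{n_pairs} of the dataset is the
#' number of rows.
#'
#' @slot pairs data.frame with columns \code{referenceId},
#'   \code{memberId}, \code{source} (one of \code{splicing},
#'   \code{orthology}, \code{naive_orthology}) and logical
#'   \code{cdsOnly} flagging UTR-less members.
#' @slot referenceIds character vector of every reference transcript id
#'   (including those with empty sets).
#' @export
setClass("AugmentationSets",
  representation(pairs = "data.frame", referenceIds = "character"))

setValidity("AugmentationSets", function(object) {
  p <- object@pairs
  need <- c("referenceId", "memberId", "source", "cdsOnly")
  if (!all(need %in% names(p))) return("pairs must have the canonical columns")
  if (nrow(p)) {
    if (any(p$referenceId == p$memberId))
      return("a reference transcript may not be a member of its own set")
    if (!all(p$source %in% c("splicing", "orthology", "naive_orthology")))
      return("unknown augmentation source")
    if (anyDuplicated(p[, c("referenceId", "memberId", "source")]))
      return("members must be unique by (reference, member, source)")
  }
  TRUE
})

setMethod("show", "AugmentationSets", function(object) {
  tab <- table(object@pairs$source)
  cat(sprintf("AugmentationSets: %d reference transcripts, %d ordered pairs\n",
              length(object@referenceIds), nrow(object@pairs)))
  for (s in names(tab)) cat(sprintf("  %s: %d\n", s, tab[[s]]))
})

#' @rdname AugmentationSets
#' @param x an \code{AugmentationSets} object.
#' @param id reference transcript id.
#' @return \code{setMembers} returns the member rows for one reference.
#' @export
setGeneric("setMembers", function(x, id) standardGeneric("setMembers"))
#' @rdname AugmentationSets
setMethod("setMembers", "AugmentationSets", function(x, id)
  x@pairs[x@pairs$referenceId == id, , drop = FALSE])
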