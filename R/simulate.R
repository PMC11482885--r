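#' Simulation configuration for the synthetic gene-family corpus
#'
#' Defaults define the desk-scale study corpus used throughout:
#' 200 gene families, 2-4 splice isoforms per gene, 3 ortholog
#' species with a 5\% per-site CDS substitution rate, ancestral genes
#' of 4-12 exons, planted 3'UTR motifs driving a continuous label
#' (effect size 1 per motif occurrence plus a log-CDS-length term,
#' Gaussian noise sd 0.5) and 10 functional classes defined by shared
#' motif modules.
#'
#' @param nFamilies number of gene families.
#' @param isoformsPerGene integer range \code{c(min, max)}.
#' @param nOrthologSpecies ortholog species count.
#' @param exonCount ancestral exon-count range.
#' @param exonLen exon-length range (nt).
#' @param intronLen intron-length range (nt).
#' @param substitutionRate per-site CDS substitution probability for
#'   orthologs.
#' @param nClasses number of functional classes (each class shares a
#'   2-motif module planted in member genes' 3'UTRs).
#' @param nFreeMotifs extra library motifs planted gene-specifically.
#' @param motifLen planted motif length.
#' @param beta per-motif effect size on the label.
#' @param gamma effect of \code{log(cds_len)} on the label.
#' @param labelNoiseSd Gaussian label noise sd.
#' @param paralogFraction fraction of families carrying a second
#'   (paralogous) gene.
#' @param seed RNG seed; fixes the whole corpus.
#' @return a \code{sim_config} list.
#' @export
simulationConfig <- function(nFamilies = 200L, isoformsPerGene = c(2L, 4L),
                             nOrthologSpecies = 3L, exonCount = c(4L, 12L),
                             exonLen = c(45L, 150L), intronLen = c(60L, 300L),
                             substitutionRate = 0.05, nClasses = 10L,
                             nFreeMotifs = 4L, motifLen = 6L, beta = 1,
                             gamma = 1, labelNoiseSd = 0.5,
                             paralogFraction = 0.2, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(nFamilies >= 1L, all(isoformsPerGene >= 1L),
            exonCount[1L] >= 4L, exonLen[1L] >= 3L * (motifLen + 2L),
            substitutionRate >= 0, substitutionRate <= 1,
            labelNoiseSd >= 0, paralogFraction >= 0, paralogFraction <= 1)
  class(cfg) <- "sim_config"
  cfg
}

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Distinct random motifs; regenerated identically from the corpus seed.
.makeMotifLibrary <- function(n, len) {
  out <- character(0)
  while (length(out) < n) {
    m <- .randSeq(len)
    if (!m %in% out) out <- c(out, m)
  }
  out
}

# Overwrite `count` non-overlapping occurrences of `motif` inside
# region [from, to] (1-based) of the sequence string.
.plantMotif <- function(seq, motif, count, from, to) {
  ml <- nchar(motif)
  taken <- integer(0)
  placed <- 0L
  tries <- 0L
  while (placed < count && tries < 50L) {
    tries <- tries + 1L
    p <- sample(from:(to - ml + 1L), 1L)
    if (any(abs(taken - p) < ml)) next
    substr(seq, p, p + ml - 1L) <- motif
    taken <- c(taken, p)
    placed <- placed + 1L
  }
  seq
}

.substitute <- function(seq, rate) {
  if (rate <= 0) return(seq)
  s <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(s)) < rate)
  for (i in hit) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1L)
  paste(s, collapse = "")
}

# Map a 0-based mature position to a 1-based genomic coordinate given
# exon starts/ends (genomic ascending) and strand.
.mature2genomic <- function(starts, ends, strandChar, p) {
  w <- ends - starts + 1L
  if (strandChar == "-") { starts <- rev(starts); ends <- rev(ends); w <- rev(w) }
  cum <- cumsum(c(0L, w))
  k <- findInterval(p, cum, rightmost.closed = FALSE)  # transcript exon
  off <- p - cum[k]
  if (strandChar == "+") starts[k] + off else ends[k] - off
}

#' Generate a synthetic gene-family corpus
#'
#' Builds, deterministically from the seed, a corpus with the
#' statistical structure the contrastive method assumes: gene families
#' with multiple splice isoforms sharing exon subsets (terminal exons
#' and reading frame retained), UTR-less CDS orthologs derived by
#' per-site substitution, planted 3'UTR motifs that linearly determine
#' a continuous label, exon-block-derived protein-domain annotations,
#' and family/functional-class annotations supporting homology-aware
#' splits and functional-class pair sampling.
#'
#' Per gene the ancestral structure is: a first exon holding the 5'UTR
#' and CDS start, internal CDS exons (lengths divisible by 3 so any
#' subset can be dropped without breaking frame), a CDS-end exon, a
#' pure-3'UTR "motif exon" carrying the planted motifs, and a 3'UTR
#' tail exon. Isoforms drop random subsets of the internal CDS exons.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @return a \code{synthetic_corpus} list: \code{models},
#'   \code{rnas}, \code{genomes}, \code{labels} (per-transcript table),
#'   \code{mapping} (reference to ortholog), \code{domains} (named list
#'   of per-transcript domain-id sets), \code{motifs}, \code{config}.
#' @export
simulateCorpus <- function(cfg = simulationConfig()) {
  withr::with_seed(cfg$seed, .simulateCorpusImpl(cfg))
}

.simulateCorpusImpl <- function(cfg) {
  nMotifs <- 2L * cfg$nClasses + cfg$nFreeMotifs
  motifs <- .makeMotifLibrary(nMotifs, cfg$motifLen)
  beta <- rep(cfg$beta, nMotifs)
  models <- list(); rnas <- list(); domains <- list()
  chromsBySpecies <- list(ref = list())
  for (s in seq_len(cfg$nOrthologSpecies))
    chromsBySpecies[[paste0("species_", s)]] <- list()
  labelRows <- list(); mapRows <- list()
  geneCounter <- 0L
  for (fam in seq_len(cfg$nFamilies)) {
    famId <- sprintf("F%04d", fam)
    classId <- sprintf("C%02d", (fam - 1L) %% cfg$nClasses + 1L)
    classMotifIdx <- 2L * ((fam - 1L) %% cfg$nClasses) + c(1L, 2L)
    nGenes <- 1L + (stats::runif(1) < cfg$paralogFraction)
    for (gi in seq_len(nGenes)) {
      geneCounter <- geneCounter + 1L
      geneId <- sprintf("G%04d", geneCounter)
      gene <- .simulateGene(cfg, geneId, famId, classId, classMotifIdx,
                            motifs, beta)
      models <- c(models, gene$models)
      rnas <- c(rnas, gene$rnas)
      domains <- c(domains, gene$domains)
      labelRows[[geneId]] <- gene$labels
      mapRows[[geneId]] <- gene$mapping
      for (sp in names(gene$chroms))
        chromsBySpecies[[sp]] <- c(chromsBySpecies[[sp]], gene$chroms[[sp]])
    }
  }
  genomes <- lapply(chromsBySpecies, function(ch)
    DNAStringSet(unlist(ch)))
  labels <- do.call(rbind, labelRows)
  rownames(labels) <- NULL
  mapping <- do.call(rbind, mapRows)
  rownames(mapping) <- NULL
  names(models) <- vapply(models, transcriptId, character(1L))
  names(rnas) <- vapply(rnas, transcriptId, character(1L))
  out <- list(models = models, rnas = rnas, genomes = genomes,
              labels = labels, mapping = mapping, domains = domains,
              motifs = motifs, config = cfg)
  class(out) <- "synthetic_corpus"
  out
}

# One gene: ancestral structure, isoforms, orthologs, labels, domains.
.simulateGene <- function(cfg, geneId, famId, classId, classMotifIdx,
                          motifs, beta) {
  E <- sample(cfg$exonCount[1L]:cfg$exonCount[2L], 1L)
  len <- sample(cfg$exonLen[1L]:cfg$exonLen[2L], E, replace = TRUE)
  internalCds <- if (E >= 5L) 2L:(E - 3L) else integer()
  len[internalCds] <- len[internalCds] - len[internalCds] %% 3L
  u5 <- sample(20L:min(100L, len[1L] - 21L), 1L)
  cdsEndExon <- E - 2L
  cdsInLast <- sample(30L:(len[cdsEndExon] - 15L), 1L)
  cdsLen <- (len[1L] - u5) + sum(len[internalCds]) + cdsInLast
  u5 <- u5 + cdsLen %% 3L          # tweak 5'UTR to make CDS frame-exact
  cdsLen <- cdsLen - cdsLen %% 3L
  M <- sum(len)
  u3 <- M - u5 - cdsLen
  seq <- .randSeq(M)
  # plant motifs inside the dedicated 3'UTR motif exon
  motifFrom <- sum(len[seq_len(E - 2L)]) + 1L
  motifTo <- motifFrom + len[E - 1L] - 1L
  plantIdx <- c(classMotifIdx,
                sample(setdiff(seq_along(motifs), classMotifIdx),
                       cfg$nFreeMotifs %/% 2L))
  for (mi in plantIdx) {
    cnt <- sample(0:3, 1L, prob = c(0.15, 0.35, 0.35, 0.15))
    if (mi %in% classMotifIdx) cnt <- max(1L, cnt)
    if (cnt > 0L) seq <- .plantMotif(seq, motifs[mi], cnt, motifFrom, motifTo)
  }
  strandChar <- sample(c("+", "-"), 1L)
  # genomic exon lengths: ascending genomic order = reversed transcript
  # order on the minus strand
  glen <- if (strandChar == "+") len else rev(len)
  intr <- sample(cfg$intronLen[1L]:cfg$intronLen[2L], E - 1L, replace = TRUE)
  gStart <- cumsum(c(51L, utils::head(glen, -1L) + intr))
  gEnd <- gStart + glen - 1L
  chromLen <- gEnd[E] + 50L
  pieces <- substring(seq, cumsum(c(1L, utils::head(len, -1L))),
                      cumsum(len))
  chromSeq <- strsplit(.randSeq(chromLen), "")[[1L]]
  for (k in seq_len(E)) {
    gi <- if (strandChar == "+") k else E + 1L - k
    piece <- if (strandChar == "+") pieces[k] else
      as.character(reverseComplement(DNAString(pieces[k])))
    chromSeq[gStart[gi]:gEnd[gi]] <- strsplit(piece, "")[[1L]]
  }
  chrom <- paste0("chr_", geneId)
  chromStr <- paste(chromSeq, collapse = "")
  g5 <- .mature2genomic(gStart, gEnd, strandChar, u5)
  g3 <- .mature2genomic(gStart, gEnd, strandChar, u5 + cdsLen - 1L)
  cdsS <- min(g5, g3); cdsE <- max(g5, g3)
  # exon indices in TRANSCRIPT order k; genomic index gi(k)
  txExonGenomicIdx <- function(k) if (strandChar == "+") k else E + 1L - k
  keepSets <- list(seq_len(E))             # canonical keeps everything
  nIso <- sample(cfg$isoformsPerGene[1L]:cfg$isoformsPerGene[2L], 1L)
  tries <- 0L
  while (length(keepSets) < nIso && tries < 25L && length(internalCds)) {
    tries <- tries + 1L
    nd <- sample.int(max(1L, length(internalCds) - 1L), 1L)
    drop <- sort(internalCds[sample.int(length(internalCds), nd)])
    keep <- setdiff(seq_len(E), drop)
    if (!any(vapply(keepSets, function(ks) identical(ks, keep), logical(1L))))
      keepSets <- c(keepSets, list(keep))
  }
  gmodels <- list(); grnas <- list(); gdom <- list(); lr <- list()
  genome1 <- DNAStringSet(stats::setNames(chromStr, chrom))
  # domain ids carried by internal exons (transcript order), 0-2 each
  domOf <- lapply(seq_len(E), function(k) {
    if (k == 1L || k >= E - 1L) return(character())
    nD <- k %% 3L
    if (nD == 0L) character() else paste0(geneId, "_e", k, "_d", seq_len(nD))
  })
  for (ii in seq_along(keepSets)) {
    keep <- keepSets[[ii]]
    txId <- sprintf("%s-%03d", geneId, 200L + ii)
    gIdx <- sort(vapply(keep, txExonGenomicIdx, integer(1L)))
    model <- TranscriptModel(
      transcriptId = txId, geneId = geneId, geneName = geneId,
      species = "ref",
      exons = GRanges(chrom, IRanges(gStart[gIdx], gEnd[gIdx]),
                      strand = strandChar),
      cdsStart = cdsS, cdsEnd = cdsE)
    rna <- extractMatureRNA(model, genome1)
    gmodels[[txId]] <- model
    grnas[[txId]] <- rna
    gdom[[txId]] <- sort(unique(unlist(domOf[keep])))
    counts <- vapply(motifs, function(m)
      Biostrings::countPattern(m, rna@sequence), numeric(1L))
    y <- sum(beta * counts) + cfg$gamma * log(segmentLengths(rna)[["cds"]]) +
      stats::rnorm(1L, sd = cfg$labelNoiseSd)
    lr[[txId]] <- data.frame(
      transcriptId = txId, geneId = geneId, familyId = famId,
      class = classId, species = "ref", canonical = (ii == 1L),
      y = y, cdsLen = segmentLengths(rna)[["cds"]],
      motifCount = sum(counts), stringsAsFactors = FALSE)
  }
  # orthologs: CDS of the canonical transcript, substituted, UTR-less
  canonical <- grnas[[1L]]
  csl <- segmentLengths(canonical)
  cdsSeq <- substr(rnaSequence(canonical), csl[["utr5"]] + 1L,
                   csl[["utr5"]] + csl[["cds"]])
  chroms <- stats::setNames(list(stats::setNames(list(chromStr), chrom)), "ref")
  mp <- list()
  for (s in seq_len(cfg$nOrthologSpecies)) {
    sp <- paste0("species_", s)
    oSeq <- .substitute(cdsSeq, cfg$substitutionRate)
    oId <- sprintf("%s-orth%d", geneId, s)
    oChrom <- paste0("chr_", geneId, "_", sp)
    # keep the canonical CDS exon structure (projected annotation):
    # per-exon CDS contributions of the canonical model, transcript order
    canEx <- exonRanges(gmodels[[1L]])
    ov <- pmax(0L, pmin(end(canEx), cdsE) - pmax(start(canEx), cdsS) + 1L)
    if (strandChar == "-") ov <- rev(ov)
    cdsPieceLens <- ov[ov > 0L]
    oIntr <- sample(cfg$intronLen[1L]:cfg$intronLen[2L],
                    length(cdsPieceLens) - 1L, replace = TRUE)
    oStart <- cumsum(c(31L, utils::head(cdsPieceLens, -1L) + oIntr))
    oEnd <- oStart + cdsPieceLens - 1L
    oChromLen <- oEnd[length(oEnd)] + 30L
    oChromSeq <- strsplit(.randSeq(oChromLen), "")[[1L]]
    oPieces <- substring(oSeq, cumsum(c(1L, utils::head(cdsPieceLens, -1L))),
                         cumsum(cdsPieceLens))
    for (k in seq_along(oPieces))
      oChromSeq[oStart[k]:oEnd[k]] <- strsplit(oPieces[k], "")[[1L]]
    oChromStr <- paste(oChromSeq, collapse = "")
    om <- TranscriptModel(
      transcriptId = oId, geneId = geneId, geneName = geneId, species = sp,
      exons = GRanges(oChrom, IRanges(oStart, oEnd), strand = "+"),
      cdsStart = oStart[1L], cdsEnd = oEnd[length(oEnd)])
    orna <- extractMatureRNA(om, DNAStringSet(stats::setNames(oChromStr, oChrom)))
    gmodels[[oId]] <- om
    grnas[[oId]] <- orna
    chroms[[sp]] <- stats::setNames(list(oChromStr), oChrom)
    for (txId in names(lr))
      mp[[paste(txId, oId)]] <- data.frame(referenceId = txId,
                                           orthologId = oId,
                                           stringsAsFactors = FALSE)
  }
  list(models = gmodels, rnas = grnas, domains = gdom,
       labels = do.call(rbind, lr),
       mapping = if (length(mp)) do.call(rbind, mp) else
         data.frame(referenceId = character(), orthologId = character()),
       chroms = chroms)
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  nref <- sum(x$labels$species == "ref")
  cat(sprintf(
    "synthetic corpus: %d families, %d reference transcripts, %d models total, %d species\n",
    length(unique(x$labels$familyId)), nref, length(x$models),
    length(x$genomes)))
  invisible(x)
}

#' Convert corpus labels to a probing task
#'
#' @param corpus a \code{synthetic_corpus}.
#' @param label \code{"y"} for the planted continuous label
#'   (regression) or \code{"class"} for the functional class
#'   (classification).
#' @return a \code{probe_task} list: \code{name}, \code{kind},
#'   \code{labels} (named vector over reference transcripts),
#'   \code{family} (named vector of family ids for homology splits).
#' @export
corpusToProbeTask <- function(corpus, label = c("y", "class")) {
  label <- match.arg(label)
  lb <- corpus$labels[corpus$labels$species == "ref", ]
  vals <- if (label == "y") stats::setNames(lb$y, lb$transcriptId)
          else stats::setNames(lb$class, lb$transcriptId)
  out <- list(name = if (label == "y") "planted_motif_property"
              else "functional_class",
              kind = if (label == "y") "regression" else "classification",
              labels = vals,
              family = stats::setNames(lb$familyId, lb$transcriptId))
  class(out) <- "probe_task"
  out
}

#' Write a corpus to disk in standard formats
#'
#' One genePred and one FASTA per species, plus label, domain and
#' ortholog-mapping TSVs, so the synthetic corpus flows through the
#' same readers as real annotation data.
#'
#' @param corpus a \code{synthetic_corpus}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeCorpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spOf <- vapply(corpus$models, speciesId, character(1L))
  for (sp in names(corpus$genomes)) {
    Biostrings::writeXStringSet(corpus$genomes[[sp]],
                                file.path(dir, paste0(sp, ".fa")))
    writeGenePred(corpus$models[spOf == sp],
                  file.path(dir, paste0(sp, ".genePred")))
  }
  utils::write.table(corpus$labels, file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(corpus$mapping, file.path(dir, "ortholog_mapping.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dom <- data.frame(
    transcriptId = rep(names(corpus$domains),
                       lengths(corpus$domains)),
    domainId = unlist(corpus$domains), row.names = NULL)
  utils::write.table(dom, file.path(dir, "domains.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write transcript models as a genePred file
#'
#' @param models list of \linkS4class{TranscriptModel}.
#' @param path output path (12-column genePred with name2).
#' @return invisibly, the path.
#' @export
writeGenePred <- function(models, path) {
  lines <- vapply(models, function(m) {
    ex <- exonRanges(m)
    coding <- isCoding(m)
    paste(c(transcriptId(m), as.character(seqnames(ex))[1L],
            as.character(strand(ex))[1L],
            min(start(ex)) - 1L, max(end(ex)),
            if (coding) m@cdsStart - 1 else min(start(ex)) - 1L,
            if (coding) m@cdsEnd else min(start(ex)) - 1L,
            length(ex),
            paste0(paste(start(ex) - 1L, collapse = ","), ","),
            paste0(paste(end(ex), collapse = ","), ","),
            0L, geneName(m)), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
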