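#' Load a corpus directory written by \code{\link{writeCorpus}}
#'
#' Reads the per-species genePred and FASTA files back through the
#' standard readers, re-extracts every mature RNA, and reassembles the
#' label, domain and ortholog-mapping tables, so a corpus on disk is
#' interchangeable with an in-memory one.
#'
#' @param dir corpus directory.
#' @return a \code{synthetic_corpus}-shaped list.
#' @export
loadCorpus <- function(dir) {
  gps <- list.files(dir, pattern = "\\.genePred$", full.names = TRUE)
  if (!length(gps)) stop("no genePred files in ", dir)
  models <- list(); rnas <- list(); genomes <- list()
  for (gp in gps) {
    sp <- sub("\\.genePred$", "", basename(gp))
    genome <- Biostrings::readDNAStringSet(file.path(dir, paste0(sp, ".fa")))
    names(genome) <- sub("\\s.*$", "", names(genome))
    ms <- readGenePred(gp, species = sp)
    rs <- lapply(ms, extractMatureRNA, genome = genome)
    models <- c(models, ms)
    rnas <- c(rnas, rs)
    genomes[[sp]] <- genome
  }
  names(rnas) <- names(models)
  labels <- utils::read.delim(file.path(dir, "labels.tsv"),
                              stringsAsFactors = FALSE)
  mapPath <- file.path(dir, "ortholog_mapping.tsv")
  mapping <- if (file.exists(mapPath))
    utils::read.delim(mapPath, stringsAsFactors = FALSE)
  else data.frame(referenceId = character(), orthologId = character())
  domPath <- file.path(dir, "domains.tsv")
  domains <- list()
  if (file.exists(domPath)) {
    dd <- utils::read.delim(domPath, stringsAsFactors = FALSE)
    domains <- split(dd$domainId, dd$transcriptId)
  }
  out <- list(models = models, rnas = rnas, genomes = genomes,
              labels = labels, mapping = mapping, domains = domains,
              motifs = character(), config = NULL)
  class(out) <- "synthetic_corpus"
  out
}
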