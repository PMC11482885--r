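test_that("genePred rows parse into transcript models", {
  path <- writeGenePredFixture()
  models <- readGenePred(path, species = "human")
  expect_length(models, 3L)
  expect_setequal(names(models), c("t1", "t2", "t3"))

  m1 <- models[["t1"]]
  expect_equal(length(exonRanges(m1)), 1L)
  expect_equal(GenomicRanges::start(exonRanges(m1)), 101L)
  expect_equal(GenomicRanges::end(exonRanges(m1)), 200L)
  expect_equal(m1@cdsStart, 131)
  expect_equal(m1@cdsEnd, 190)

  # bin column auto-detected; name2 becomes the gene name
  m2 <- models[["t2"]]
  expect_equal(geneName(m2), "GENE2")
  expect_equal(length(exonRanges(m2)), 2L)
  expect_false(isCoding(m2))     # cdsStart == cdsEnd

  expect_equal(as.character(GenomicRanges::strand(exonRanges(models[["t3"]]))),
               c("-", "-"))
})

test_that("malformed genePred rows are rejected or skipped", {
  bad <- tempfile()
  writeLines("tx\tchr1\t+\t0\t100\t0\t0\t2\t0,40,60,\t30,50,", bad)
  expect_error(readGenePred(bad), "exonCount")

  skippy <- tempfile()
  writeLines(c("ok\tchr1\t+\t0\t100\t0\t0\t1\t0,\t100,",
               "bad\tchr1\t+\t0\t100\t0\t0\t1\t90,\t40,"), skippy)
  expect_warning(models <- readGenePred(skippy), "malformed")
  expect_length(models, 1L)
  expect_error(readGenePred(tempfile()), "cannot read")
})

test_that("BED12 records parse with blocks as exons and thick as CDS", {
  path <- writeBed12Fixture()
  models <- readTogaBed(path, species = "sp1")
  expect_length(models, 4L)

  m <- models[["gA.tx1"]]
  expect_equal(length(exonRanges(m)), 2L)
  expect_equal(sum(GenomicRanges::width(exonRanges(m))), 110L)
  expect_true(isCoding(m))
  expect_equal(geneId(m), "gA")

  # thickStart == thickEnd means non-coding
  expect_false(isCoding(models[["gB.tx1"]]))
  expect_equal(length(exonRanges(models[["gC.tx1"]])), 3L)
})

test_that("mature RNA extraction concatenates exons and handles strand", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ATGCAAAAGGTA"))
  m <- TranscriptModel("tx", "g", exons = GRanges("chr1",
    IRanges::IRanges(c(1, 9), c(4, 12)), strand = "+"))
  rna <- extractMatureRNA(m, genome)
  expect_equal(rnaSequence(rna), "ATGCGGTA")
  expect_equal(junctions(rna), 4L)

  mneg <- TranscriptModel("txn", "g", exons = GRanges("chr1",
    IRanges::IRanges(1, 4), strand = "-"))
  expect_equal(rnaSequence(extractMatureRNA(mneg, genome)), "GCAT")

  # minus-strand multi-exon extraction equals revcomp of plus extraction
  mp <- TranscriptModel("p", "g", exons = GRanges("chr1",
    IRanges::IRanges(c(1, 6), c(3, 10)), strand = "+"))
  mm <- TranscriptModel("m", "g", exons = GRanges("chr1",
    IRanges::IRanges(c(1, 6), c(3, 10)), strand = "-"))
  expect_equal(
    rnaSequence(extractMatureRNA(mm, genome)),
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(rnaSequence(extractMatureRNA(mp, genome))))))
})

test_that("CDS annotation maps to mature codon-start positions", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(rep("A", 20), collapse = "")))
  # CDS spans mature (0-based) positions [2, 11): genomic 1-based 3..11
  m <- TranscriptModel("tx", "g", exons = GRanges("chr1",
    IRanges::IRanges(1, 20), strand = "+"), cdsStart = 3, cdsEnd = 11)
  rna <- extractMatureRNA(m, genome)
  expect_equal(codonStarts(rna), c(2L, 5L, 8L))
  expect_equal(unname(segmentLengths(rna)), c(2L, 9L, 9L))
  expect_error(extractMatureRNA(
    TranscriptModel("off", "g", exons = GRanges("chrX",
      IRanges::IRanges(1, 5), strand = "+")), genome), "chromosome")
})

test_that("six-track encoding follows the fixed channel conventions", {
  cds9 <- MatureRNA("c", "ATGGCCTAA", codonStarts = c(0, 3, 6),
                    utr5Len = 0, cdsLen = 9, utr3Len = 0)
  enc <- encodeSixTrack(cds9)
  expect_equal(enc@mat[, 6L], c(1, 0, 0, 1, 0, 0, 1, 0, 0))
  expect_equal(sum(enc@mat[, 5L]), 0)
  expect_equal(enc@mat[1, 1:4], c(1, 0, 0, 0))     # A one-hot

  withN <- encodeSixTrack(MatureRNA("n", "AANA"))
  expect_equal(unname(withN@mat[3L, 1:4]), c(0, 0, 0, 0))

  twoExon <- MatureRNA("j", "ACGTACGT", junctions = 4L)
  encJ <- encodeSixTrack(twoExon)
  expect_equal(which(encJ@mat[, 5L] == 1), 5L)     # 0-based index 4

  # truncation drops the 3' end and keeps the 5' features
  tr <- encodeSixTrack(twoExon, maxLen = 6L)
  expect_equal(length(tr), 6L)
  expect_equal(which(tr@mat[, 5L] == 1), 5L)
})

test_that("decode inverts encode and flags invalid encodings", {
  rna <- MatureRNA("x", "ATGCGGTA", junctions = 4L)
  dec <- decodeSixTrack(encodeSixTrack(rna))
  expect_equal(rnaSequence(dec), "ATGCGGTA")
  expect_equal(junctions(dec), 4L)

  z <- encodeSixTrack(MatureRNA("z", "ACGT"))
  m <- z@mat; m[2L, 1:4] <- 0
  expect_equal(rnaSequence(decodeSixTrack(new("SixTrackEncoding", mat = m,
                                              mask = z@mask))), "ANGT")
  bad <- z@mat; bad[1L, 2L] <- 1
  expect_error(new("SixTrackEncoding", mat = bad, mask = z@mask),
               "sum to <= 1")

  long <- MatureRNA("l", paste(rep("ACGT", 10), collapse = ""))
  expect_equal(length(decodeSixTrack(encodeSixTrack(long, maxLen = 12L))), 12L)
})

test_that("encode/decode round-trips exactly on random transcripts", {
  withr::with_seed(99, {
    for (i in seq_len(1000L)) {
      rna <- randomMatureRNA(paste0("r", i))
      dec <- decodeSixTrack(encodeSixTrack(rna, maxLen = 128L))
      expect_identical(rnaSequence(dec), rnaSequence(rna))
      expect_identical(junctions(dec), junctions(rna))
      expect_identical(codonStarts(dec), codonStarts(rna))
    }
  })
})

test_that("track sums conserve junction and codon counts before truncation", {
  withr::with_seed(7, {
    for (i in 1:50) {
      rna <- randomMatureRNA()
      enc <- encodeSixTrack(rna, maxLen = 200L)
      expect_equal(sum(enc@mat[, 5L]), length(junctions(rna)))
      expect_equal(sum(enc@mat[, 6L]),
                   unname(segmentLengths(rna)[["cds"]]) / 3)
    }
  })
})
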