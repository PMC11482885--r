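# helpers to build tiny model/rna collections by hand
.toyModels <- function(spec) {
  # spec: data.frame(tx, gene, species)
  out <- lapply(seq_len(nrow(spec)), function(i)
    TranscriptModel(spec$tx[i], spec$gene[i], geneName = spec$gene[i],
                    species = spec$species[i],
                    exons = GRanges("chr1", IRanges::IRanges(1, 30),
                                    strand = "+")))
  names(out) <- spec$tx
  out
}

test_that("splicing sets contain exactly the other isoforms of the gene", {
  models <- .toyModels(data.frame(
    tx = c("t1", "t2", "t3", "s1", "a1", "a2", "b1", "b2"),
    gene = c("G", "G", "G", "S", "A", "A", "B", "B"),
    species = "ref"))
  sets <- buildSplicingSets(models)
  expect_setequal(setMembers(sets, "t1")$memberId, c("t2", "t3"))
  expect_equal(nrow(setMembers(sets, "s1")), 0L)       # single isoform
  # 2 genes x 2 isoforms -> 4 sets of size 1
  for (id in c("a1", "a2", "b1", "b2"))
    expect_equal(nrow(setMembers(sets, id)), 1L)
  # symmetric closure for splicing
  p <- sets@pairs
  for (k in seq_len(nrow(p)))
    expect_true(any(p$referenceId == p$memberId[k] &
                    p$memberId == p$referenceId[k]))
})

test_that("orthology members append with source and UTR flags", {
  ref <- .toyModels(data.frame(tx = c("t1", "t2"), gene = "G",
                               species = "ref"))
  orth <- list(
    o1 = TranscriptModel("o1", "G", species = "sp1",
      exons = GRanges("c", IRanges::IRanges(1, 30), strand = "+"),
      cdsStart = 1, cdsEnd = 30),              # CDS-only
    o2 = TranscriptModel("o2", "G", species = "sp2",
      exons = GRanges("c", IRanges::IRanges(1, 30), strand = "+"),
      cdsStart = 10, cdsEnd = 21))             # has UTRs
  sets <- buildSplicingSets(ref)
  mapping <- data.frame(referenceId = "t1", orthologId = c("o1", "o2"))
  sets2 <- buildOrthologySets(sets, mapping, orth)
  mem <- setMembers(sets2, "t1")
  om <- mem[mem$source == "orthology", ]
  expect_equal(nrow(om), 2L)
  expect_true(om$cdsOnly[om$memberId == "o1"])
  expect_false(om$cdsOnly[om$memberId == "o2"])

  # empty mapping leaves sets unchanged
  expect_identical(buildOrthologySets(sets, mapping[0, ], orth)@pairs,
                   sets@pairs)
  # unknown ortholog id -> warning, skipped
  expect_warning(
    s3 <- buildOrthologySets(sets, data.frame(referenceId = "t1",
                                              orthologId = "nope"), orth),
    "unknown ortholog")
  expect_equal(nrow(s3@pairs), nrow(sets@pairs))
})

test_that("naive orthology pools same-named genes across species only", {
  models <- .toyModels(data.frame(
    tx = c("h1", "h2", "m1", "u1"),
    gene = c("TP53", "TP53", "TP53", "tp53"),
    species = c("human", "human", "mouse", "fish")))
  sets <- buildSplicingSets(models)
  sets2 <- mergeNaiveOrthology(sets, models)
  mem <- setMembers(sets2, "h1")
  naive <- mem[mem$source == "naive_orthology", ]
  expect_equal(naive$memberId, "m1")       # exact case-sensitive match
  expect_false("u1" %in% mem$memberId)
})

test_that("the chimeric UTR transform splices reference UTRs onto an ortholog CDS", {
  iso <- MatureRNA("iso", "AAATGGGGTAAGG", junctions = integer(),
                   codonStarts = c(2, 5, 8), utr5Len = 2, cdsLen = 9,
                   utr3Len = 2)
  ocds <- MatureRNA("orth", "ATGCCCTAA", codonStarts = c(0, 3, 6),
                    utr5Len = 0, cdsLen = 9, utr3Len = 0)
  ch <- utrCombinationTransform(iso, ocds)
  expect_equal(rnaSequence(ch), "AAATGCCCTAAGG")
  expect_equal(codonStarts(ch), c(2L, 5L, 8L))
  expect_equal(unname(segmentLengths(ch)), c(2L, 9L, 2L))

  # empty UTRs -> chimera equals the ortholog CDS
  bare <- MatureRNA("bare", "ATGTTTTAA", codonStarts = c(0, 3, 6),
                    utr5Len = 0, cdsLen = 9, utr3Len = 0)
  expect_equal(rnaSequence(utrCombinationTransform(bare, ocds)),
               rnaSequence(ocds))

  # length arithmetic: 7 + |ortholog CDS| + 4
  iso2 <- MatureRNA("i2", paste(rep("A", 20), collapse = ""),
                    codonStarts = 7 + 3 * (0:2), utr5Len = 7, cdsLen = 9,
                    utr3Len = 4)
  expect_equal(length(utrCombinationTransform(iso2, ocds)), 20L)
  nc <- MatureRNA("nc", "ACGTACGT")
  expect_error(utrCombinationTransform(nc, ocds), "coding")
})

test_that("masking augmentation zeroes only nucleotide tracks, out of place", {
  rna <- MatureRNA("m", paste(rep("ACGT", 25), collapse = ""),
                   junctions = c(10, 50))
  enc <- encodeSixTrack(rna)
  m0 <- maskAugment(enc, fraction = 0)
  expect_identical(m0@mat, enc@mat)
  m1 <- maskAugment(enc, fraction = 1, seed = 3)
  expect_true(all(m1@mat[, 1:4] == 0))
  expect_identical(m1@mat[, 5:6], enc@mat[, 5:6])
  m30 <- maskAugment(enc, fraction = 0.30, seed = 5)
  expect_equal(sum(rowSums(m30@mat[, 1:4]) == 0), 30L)
  expect_identical(enc@mat, encodeSixTrack(rna)@mat)  # input untouched
  expect_error(maskAugment(enc, fraction = 1.2), "fraction")
})

test_that("positive-pair sampling is deterministic, resamples across epochs, and falls back", {
  spec <- data.frame(tx = c("t1", "t2", "t3", "t4", "lone"),
                     gene = c("G", "G", "G", "G", "L"), species = "ref")
  models <- .toyModels(spec)
  rnas <- lapply(spec$tx, function(id) MatureRNA(id, paste(
    sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")))
  names(rnas) <- spec$tx
  sets <- buildSplicingSets(models)

  p1 <- samplePositivePair("t1", sets, rnas, epoch = 3, seed = 7)
  p2 <- samplePositivePair("t1", sets, rnas, epoch = 3, seed = 7)
  expect_identical(p1$memberId, p2$memberId)
  expect_identical(trackMatrix(p1$x2), trackMatrix(p2$x2))

  drawn <- vapply(1:100, function(e)
    samplePositivePair("t1", sets, rnas, epoch = e, seed = 7)$memberId,
    character(1L))
  expect_gt(length(unique(drawn)), 1L)       # epoch resampling

  # empty set -> masked-self fallback
  pf <- samplePositivePair("lone", sets, rnas, epoch = 1, seed = 7)
  expect_equal(pf$source, "masking")
  expect_equal(pf$weight, 1.0)
  expect_equal(sum(rowSums(trackMatrix(pf$x2)[, 1:4]) == 0), 9L)

  # uniform draw over the 3 members across epochs
  freq <- table(vapply(1:3000, function(e)
    samplePositivePair("t1", sets, rnas, epoch = e, seed = 1)$memberId,
    character(1L))) / 3000
  expect_true(all(abs(freq - 1 / 3) < 0.03))
})

test_that("orthology draws are weighted and pass through the UTR transform", {
  iso <- MatureRNA("t1", "AAATGGGGTAAGG", codonStarts = c(2, 5, 8),
                   utr5Len = 2, cdsLen = 9, utr3Len = 2)
  ocds <- MatureRNA("o1", "ATGCCCTAA", codonStarts = c(0, 3, 6),
                    utr5Len = 0, cdsLen = 9, utr3Len = 0)
  sets <- new("AugmentationSets",
              pairs = data.frame(referenceId = "t1", memberId = "o1",
                                 source = "orthology", cdsOnly = TRUE),
              referenceIds = "t1")
  p <- samplePositivePair("t1", sets, list(t1 = iso, o1 = ocds),
                          epoch = 1, seed = 2, orthologyWeight = 0.8)
  expect_equal(p$weight, 0.8)
  expect_equal(length(p$x2), 13L)            # chimera keeps reference UTRs
  dec <- decodeSixTrack(p$x2)
  expect_equal(rnaSequence(dec), "AAATGCCCTAAGG")
})

test_that("pair counting is ordered and per-source", {
  models <- .toyModels(data.frame(tx = c("t1", "t2", "t3"), gene = "G",
                                  species = "ref"))
  sets <- buildSplicingSets(models)
  st <- countPairs(sets)
  expect_equal(st$n_pairs, 6L)               # 3 x 2 ordered
  expect_equal(st$perSource$splicing, 6L)
  expect_equal(st$n_transcripts, 3L)

  empty <- buildSplicingSets(.toyModels(data.frame(
    tx = c("a", "b"), gene = c("A", "B"), species = "ref")))
  expect_equal(countPairs(empty)$n_pairs, 0L)

  path <- tempfile(fileext = ".tsv")
  writePairManifest(sets, path)
  tb <- read.delim(path)
  expect_equal(nrow(tb), 6L)
  expect_true(all(tb$weight == 1.0))
})
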