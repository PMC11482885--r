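test_that("corpus generation is deterministic and respects count bounds", {
  cfg <- simulationConfig(nFamilies = 10L, isoformsPerGene = c(2L, 4L),
                          paralogFraction = 0, seed = 21L)
  c1 <- simulateCorpus(cfg)
  c2 <- simulateCorpus(cfg)
  expect_identical(c1$labels, c2$labels)
  expect_identical(vapply(c1$rnas, rnaSequence, character(1L)),
                   vapply(c2$rnas, rnaSequence, character(1L)))
  nRef <- sum(c1$labels$species == "ref")
  expect_gte(nRef, 10L)                # at least one isoform per gene
  expect_lte(nRef, 40L)                # at most 4 per gene
  expect_equal(length(unique(c1$labels$geneId)), 10L)
})

test_that("zero substitution rate reproduces the reference CDS in orthologs", {
  cfg <- simulationConfig(nFamilies = 3L, substitutionRate = 0,
                          paralogFraction = 0, seed = 2L)
  corpus <- simulateCorpus(cfg)
  lb <- corpus$labels[corpus$labels$species == "ref", ]
  for (g in unique(lb$geneId)) {
    can <- corpus$rnas[[lb$transcriptId[lb$geneId == g & lb$canonical]]]
    sl <- segmentLengths(can)
    cds <- substr(rnaSequence(can), sl[["utr5"]] + 1L,
                  sl[["utr5"]] + sl[["cds"]])
    orth <- corpus$rnas[[paste0(g, "-orth1")]]
    expect_identical(rnaSequence(orth), cds)
    # orthologs are UTR-less (CDS over the full length)
    expect_equal(unname(segmentLengths(orth)[["cds"]]), length(orth))
  }
})

test_that("ortholog divergence tracks the configured substitution rate", {
  cfg <- simulationConfig(nFamilies = 4L, exonCount = c(12L, 14L),
                          exonLen = c(150L, 190L), substitutionRate = 0.05,
                          paralogFraction = 0, seed = 9L)
  corpus <- simulateCorpus(cfg)
  lb <- corpus$labels[corpus$labels$species == "ref", ]
  rates <- c()
  for (g in unique(lb$geneId)) {
    can <- corpus$rnas[[lb$transcriptId[lb$geneId == g & lb$canonical]]]
    sl <- segmentLengths(can)
    cds <- strsplit(substr(rnaSequence(can), sl[["utr5"]] + 1L,
                           sl[["utr5"]] + sl[["cds"]]), "")[[1L]]
    for (s in 1:3) {
      orth <- strsplit(rnaSequence(corpus$rnas[[paste0(g, "-orth", s)]]),
                       "")[[1L]]
      expect_gte(length(cds), 1000L)
      rates <- c(rates, mean(cds != orth))
    }
  }
  expect_true(all(abs(rates - 0.05) < 0.02))
})

test_that("all isoforms of a gene share exons with the canonical transcript", {
  corpus <- smallCorpus()
  lb <- corpus$labels[corpus$labels$species == "ref", ]
  for (g in unique(lb$geneId)) {
    tx <- lb$transcriptId[lb$geneId == g]
    exSets <- lapply(tx, function(id) {
      ex <- exonRanges(corpus$models[[id]])
      paste(GenomicRanges::start(ex), GenomicRanges::end(ex))
    })
    common <- Reduce(intersect, exSets)
    expect_gte(length(common), 1L)
  }
})

test_that("the planted label is recoverable from true motif counts", {
  corpus <- bigCorpus()
  lb <- corpus$labels[corpus$labels$species == "ref", ]
  expect_gte(nrow(lb), 1500L)
  counts <- t(vapply(lb$transcriptId, function(id)
    vapply(corpus$motifs, function(m)
      Biostrings::countPattern(m, corpus$rnas[[id]]@sequence),
      numeric(1L)), numeric(length(corpus$motifs))))
  fit <- stats::lm(lb$y ~ counts)
  expect_gte(summary(fit)$r.squared, 0.8)
  # fitting the full generative model (counts + log CDS length)
  # recovers the per-motif effects within 2 standard errors of beta = 1;
  # counts alone are slightly confounded because longer CDSs carry more
  # accidental motif matches
  full <- stats::lm(lb$y ~ counts + log(lb$cdsLen))
  sm <- summary(full)$coefficients
  k <- length(corpus$motifs)
  betas <- sm[2:(k + 1L), 1L]; ses <- sm[2:(k + 1L), 2L]
  expect_true(mean(abs(betas - 1) <= 2 * ses) > 0.9)
})

test_that("probe tasks carry labels and family ids for every transcript", {
  corpus <- smallCorpus()
  reg <- corpusToProbeTask(corpus, "y")
  expect_equal(reg$kind, "regression")
  expect_true(all(is.finite(reg$labels)))
  expect_identical(names(reg$labels), names(reg$family))
  cls <- corpusToProbeTask(corpus, "class")
  expect_equal(cls$kind, "classification")
  expect_lte(length(unique(cls$labels)), corpus$config$nClasses)
})

test_that("a corpus written to disk reloads through the standard readers", {
  cfg <- simulationConfig(nFamilies = 4L, seed = 31L, paralogFraction = 0)
  corpus <- simulateCorpus(cfg)
  dir <- tempfile()
  writeCorpus(corpus, dir)
  expect_true(file.exists(file.path(dir, "ref.genePred")))
  expect_true(file.exists(file.path(dir, "ref.fa")))
  back <- loadCorpus(dir)
  expect_setequal(names(back$rnas), names(corpus$rnas))
  for (id in names(corpus$rnas)) {
    expect_identical(rnaSequence(back$rnas[[id]]),
                     rnaSequence(corpus$rnas[[id]]))
    expect_identical(junctions(back$rnas[[id]]),
                     junctions(corpus$rnas[[id]]))
    expect_identical(codonStarts(back$rnas[[id]]),
                     codonStarts(corpus$rnas[[id]]))
  }
  expect_equal(nrow(back$labels), nrow(corpus$labels))
  expect_setequal(names(back$domains), names(corpus$domains))
})

test_that("domain annotations derive from retained internal exons", {
  corpus <- smallCorpus()
  lb <- corpus$labels[corpus$labels$species == "ref", ]
  # a transcript that drops exons can only lose domains, never gain
  for (g in unique(lb$geneId)[1:10]) {
    tx <- lb$transcriptId[lb$geneId == g]
    can <- tx[lb$canonical[match(tx, lb$transcriptId)]]
    canDom <- corpus$domains[[can]]
    for (id in tx)
      expect_true(all(corpus$domains[[id]] %in% canDom))
  }
})
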