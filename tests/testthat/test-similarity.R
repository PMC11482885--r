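test_that("embedding similarity is 1 - log(L2) with an epsilon floor", {
  e0 <- c(0, 0, 0)
  expect_equal(embeddingSimilarity(e0, c(1, 0, 0)), 1)          # distance 1
  expect_equal(embeddingSimilarity(e0, c(exp(1), 0, 0)), 0)     # distance e
  expect_equal(embeddingSimilarity(e0, e0), 1 - log(1e-8),
               tolerance = 1e-12)                                # ~19.42
  expect_error(embeddingSimilarity(c(1, 2), c(1, 2, 3)), "dimensions")
  # symmetric and strictly decreasing in distance above the floor
  withr::with_seed(2, {
    a <- rnorm(5); b <- rnorm(5)
    expect_equal(embeddingSimilarity(a, b), embeddingSimilarity(b, a))
    ds <- c(0.01, 0.1, 1, 5, 50)
    sims <- vapply(ds, function(d)
      embeddingSimilarity(rep(0, 2), c(d, 0)), numeric(1L))
    expect_true(all(diff(sims) < 0))
  })
})

test_that("set Jaccard covers the enumerated cases", {
  expect_equal(jaccardIndex(c("A", "B"), c("B", "C")), 1 / 3)
  expect_equal(jaccardIndex(c("A", "B"), c("B", "A")), 1)
  expect_equal(jaccardIndex(c("A"), c("B")), 0)
  expect_equal(jaccardIndex(character(), character()), 1)   # both empty
  expect_equal(jaccardIndex(character(), "A"), 0)
})

test_that("interval Jaccard counts base pairs and ignores interval splitting", {
  g <- function(s, e) GRanges("chr1", IRanges::IRanges(s, e), strand = "+")
  # [0,100) vs [50,150) in 0-based half-open = 1-based [1,100], [51,150]
  expect_equal(intervalJaccard(g(1, 100), g(51, 150)), 1 / 3)
  expect_equal(intervalJaccard(g(c(1, 21), c(10, 30)),
                               g(c(1, 21), c(10, 30))), 1)
  # {[0,10),[20,30)} vs {[5,25)}: intersection {5..9} u {20..24} = 10,
  # union {0..29} = 30 (by direct base enumeration)
  expect_equal(intervalJaccard(g(c(1, 21), c(10, 30)), g(6, 25)), 1 / 3)
  # invariance to splitting the same covered bases
  expect_equal(intervalJaccard(g(c(1, 11), c(10, 100)), g(51, 150)),
               intervalJaccard(g(1, 100), g(51, 150)))
  expect_warning(
    v <- intervalJaccard(g(1, 10),
                         GRanges("chr2", IRanges::IRanges(1, 10))),
    "different chromosomes")
  expect_equal(v, 0)
})

test_that("pair-group sampling is seeded, grouped and scales down", {
  corpus <- smallCorpus()
  p1 <- samplePairGroups(corpus, nIntrageneGenes = 10L, nIntergene = 20L,
                         nGoTerms = 5L, pairsPerTerm = 3L, seed = 4L)
  p2 <- samplePairGroups(corpus, nIntrageneGenes = 10L, nIntergene = 20L,
                         nGoTerms = 5L, pairsPerTerm = 3L, seed = 4L)
  expect_identical(p1, p2)
  expect_setequal(unique(p1$group), c("intragene", "intergene", "same_GO"))
  expect_equal(sum(p1$group == "intergene"), 20L)

  # a gene with k isoforms contributes choose(k, 2) intragene pairs
  lb <- corpus$labels[corpus$labels$species == "ref", ]
  byGene <- table(lb$geneId)
  ig <- p1[p1$group == "intragene", ]
  for (gid in unique(ig$geneId))
    expect_equal(sum(ig$geneId == gid), choose(byGene[[gid]], 2L))

  # intergene and same_GO pairs never join genes of one family
  famOf <- stats::setNames(lb$familyId, lb$transcriptId)
  non <- p1[p1$group != "intragene", ]
  expect_true(all(famOf[non$id1] != famOf[non$id2]))
})

test_that("similarity reports fill metrics and flat groups test as null", {
  corpus <- smallCorpus()
  withr::with_seed(3, {
    ids <- corpus$labels$transcriptId[corpus$labels$species == "ref"]
    emb <- matrix(rnorm(length(ids) * 8), length(ids), 8,
                  dimnames = list(ids, NULL))
  })
  pairs <- samplePairGroups(corpus, nIntrageneGenes = 10L,
                            nIntergene = 30L, nGoTerms = 5L,
                            pairsPerTerm = 5L, seed = 1L)
  rep <- similarityReport(pairs, emb, corpus$domains, corpus$models)
  expect_true(all(c("embeddingScore", "domainJaccard", "cdsJaccard",
                    "sequenceJaccard") %in% names(rep$pairs)))
  expect_true(all(rep$pairs$domainJaccard >= 0 &
                  rep$pairs$domainJaccard <= 1))
  expect_true(all(rep$pairs$cdsJaccard >= 0 & rep$pairs$cdsJaccard <= 1,
                  na.rm = TRUE))
  # random embeddings: no group separation expected
  ps <- vapply(rep$groupTests, function(t) t$p, numeric(1L))
  expect_true(all(ps > 0.001))
})

test_that("isoform clustering merges identical embeddings first", {
  emb <- rbind(a = c(0, 0), b = c(0, 0), c = c(10, 10))
  cl <- clusterIsoforms(emb)
  # the identical pair joins at the lowest height
  first <- cl$hclust$merge[1L, ]
  expect_setequal(abs(first), c(1L, 2L))
  # normalized similarity has max 1 on the diagonal
  expect_true(all(diag(cl$similarity) == max(cl$similarity)))
  expect_true(grepl("^\\(", cl$tree))        # newick serialization
  expect_error(clusterIsoforms(emb[1L, , drop = FALSE]), "two isoforms")
})

test_that("clustering recovers a planted two-module structure", {
  withr::with_seed(12, {
    m1 <- matrix(rnorm(3 * 6, mean = 0, sd = 0.1), 3, 6)
    m2 <- matrix(rnorm(3 * 6, mean = 4, sd = 0.1), 3, 6)
    emb <- rbind(m1, m2)
    rownames(emb) <- paste0("iso", 1:6)
    cl <- clusterIsoforms(emb)
    cut <- stats::cutree(cl$hclust, k = 2L)
    expect_equal(length(unique(cut[1:3])), 1L)
    expect_equal(length(unique(cut[4:6])), 1L)
    expect_false(cut[1L] == cut[4L])
  })
})

test_that("exon deletion deltas are zero for the no-op and non-negative otherwise", {
  corpus <- smallCorpus()
  enc <- buildEncoder("selective",
                      ssmConfig(dModel = 16L, dState = 4L, nLayers = 1L,
                                maxLen = 2048L), seed = 8L)
  lb <- corpus$labels[corpus$labels$species == "ref", ]
  id <- lb$transcriptId[lb$canonical][1L]
  model <- corpus$models[[id]]
  genome <- corpus$genomes[["ref"]]
  d0 <- exonDeletionDelta(model, 0L, genome, enc)
  expect_equal(as.numeric(d0), 0)
  d1 <- exonDeletionDelta(model, 2L, genome, enc)
  expect_gte(as.numeric(d1), 0)
  expect_false(is.null(attr(d1, "frameBroken")))
  single <- TranscriptModel("s", "g", exons = GRanges(
    names(genome)[1L], IRanges::IRanges(1, 30), strand = "+"))
  expect_error(exonDeletionDelta(single, 1L, genome, enc), "only exon")
})
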