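# Shared fixtures and independent oracles. Expensive objects (corpora,
# trained encoders) are built once per test run and memoised here.

.fixtureEnv <- new.env(parent = emptyenv())

memoFixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureEnv))
    assign(name, builder(), envir = .fixtureEnv)
  get(name, envir = .fixtureEnv)
}

# ---- annotation fixtures --------------------------------------------------

writeGenePredFixture <- function() {
  path <- tempfile(fileext = ".genePred")
  writeLines(c(
    # plain 10-column row: single exon, coding
    "t1\tchr1\t+\t100\t200\t130\t190\t1\t100,\t200,",
    # extended row with leading bin column and name2
    "585\tt2\tchr1\t+\t100\t400\t100\t100\t2\t100,300,\t200,400,\t0\tGENE2\tnone\tnone\t-1,-1,",
    # minus-strand two-exon row
    "t3\tchr2\t-\t50\t250\t60\t240\t2\t50,150,\t100,250,"
  ), path)
  path
}

writeBed12Fixture <- function() {
  path <- tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t1000\t1200\tgA.tx1\t0\t+\t1030\t1150\t0\t2\t50,60,\t0,140,",
    "chr1\t2000\t2300\tgB.tx1\t0\t-\t2000\t2000\t0\t2\t80,70,\t0,230,",
    "chr2\t100\t400\tgC.tx1\t0\t+\t150\t370\t0\t3\t60,50,40,\t0,120,260,",
    "chr2\t500\t700\tgD.tx1\t0\t+\t520\t680\t0\t1\t200,\t0,"
  ), path)
  path
}

# Random coherent MatureRNA for round-trip properties.
randomMatureRNA <- function(id = "r") {
  L <- sample(6:80, 1L)
  coding <- runif(1) < 0.7
  if (coding) {
    cds <- 3L * sample(1:(max(1L, (L - 2L) %/% 3L)), 1L)
    u5 <- sample(0:(L - cds), 1L)
    u3 <- L - u5 - cds
    codon <- u5 + 3L * (seq_len(cds %/% 3L) - 1L)
  } else {
    u5 <- 0L; cds <- 0L; u3 <- L; codon <- integer()
  }
  nJunc <- sample(0:min(4L, L - 1L), 1L)
  junc <- sort(sample(seq_len(L - 1L), nJunc))
  seq <- paste(sample(c("A", "C", "G", "T", "N"), L, replace = TRUE,
                      prob = c(.24, .24, .24, .24, .04)), collapse = "")
  MatureRNA(id, seq, junctions = junc, codonStarts = codon,
            utr5Len = u5, cdsLen = cds, utr3Len = u3)
}

# ---- independent DCL oracle (naive per-anchor double loop) ---------------

naiveDCL <- function(Z1, Z2, w, tau) {
  N <- nrow(Z1)
  S <- rbind(Z1, Z2)
  viewOf <- function(a) if (a <= N) 1L else 2L
  sampleOf <- function(a) if (a <= N) a else a - N
  total <- 0
  for (a in seq_len(2L * N)) {
    i <- sampleOf(a)
    za <- S[a, ]
    neg <- 0
    for (k in seq_len(N)) {
      if (k == i) next
      neg <- neg + exp(sum(za * Z1[k, ]) / tau) +
        exp(sum(za * Z2[k, ]) / tau)
    }
    pos <- w[i] * sum(Z1[i, ] * Z2[i, ]) / tau
    total <- total + log(neg) - pos
  }
  total / (2 * N)
}

unitRows <- function(M) M / sqrt(rowSums(M^2))

# ---- shared corpora -------------------------------------------------------

# Small corpus for unit tests (fast).
smallCorpus <- function() memoFixture("smallCorpus", function()
  simulateCorpus(simulationConfig(nFamilies = 30L, seed = 11L)))

# Large corpus for the generator-recoverability oracle (n ~ 2,000).
bigCorpus <- function() memoFixture("bigCorpus", function()
  simulateCorpus(simulationConfig(nFamilies = 600L, seed = 7L)))

# The 200-family study corpus plus a DCL-pre-trained micro encoder and
# its embeddings, shared by the representation-recovery and similarity
# acceptance checks.
microRun <- function() memoFixture("microRun", function() {
  corpus <- simulateCorpus(simulationConfig(nFamilies = 200L, seed = 5L))
  cfg <- trainConfig(batchSize = 16L, epochs = 4L, lr = 1e-3, seed = 1L,
                     objective = "cl", maxLen = 1536L,
                     includeMasking = FALSE)
  state <- pretrain(corpus, cfg)
  refIds <- corpus$labels$transcriptId[corpus$labels$species == "ref"]
  emb <- embedCorpus(state$encoder, corpus$rnas[refIds])
  untrained <- buildEncoder("selective", presetConfig("micro", maxLen = 1536L),
                            seed = 1L)
  emb0 <- embedCorpus(untrained, corpus$rnas[refIds])
  list(corpus = corpus, state = state, encoder = state$encoder,
       refIds = refIds, emb = emb, untrained = untrained, emb0 = emb0)
})
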