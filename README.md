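# rnaclr

Self-supervised, biologically motivated contrastive pre-training for
**mature RNA** representations, in R.

Supervised models for mRNA properties (half-life, ribosome load,
localization) are starved for labels, and genomic foundation models trained
with text-style objectives spend most of their capacity on unconstrained
sequence. `rnaclr` implements the alternative: treat sequences that are
*biologically* related — splice isoforms of one gene, and orthologous
transcripts produced by speciation — as views of the same underlying
function, and learn an embedding that pulls them together while pushing
unrelated transcripts apart.

The package covers the whole pipeline at desk scale:

* **Data layer** — genePred and BED12 (projected-ortholog) readers, FASTA
  genomes, mature-RNA assembly (exon concatenation, strand handling, UTR/CDS
  segmentation), and the six-track encoding: four one-hot nucleotide
  channels plus splice-junction and codon-start indicator channels.
* **Pair construction** — splicing / orthology / naive-orthology
  augmentation sets, the chimeric UTR transform (reference UTRs wrapped
  around a UTR-less ortholog CDS), 30% masking augmentation, deterministic
  per-epoch pair sampling, and pair accounting.
* **Encoder** — a selective state-space sequence model,

  h_t = exp(Δ_t A) h_(t−1) + Δ_t B_t x_t,  y_t = C_tᵀ h_t,

  with input-dependent Δ, B, C (content-based selectivity), negative-real
  diagonal A, zero-order-hold discretization, gated blocks with residual
  connections, masked mean pooling, and an L2-normalized MLP projection
  head used only during pre-training. Forward and backward passes are
  hand-written (batched C++ scan kernel with analytic gradients, verified
  against finite differences); a sequential recurrence and an
  associative-scan implementation serve as oracles. Parameter-matched
  non-selective (LTI) and CNN baselines share the same embedding contract.
* **Objectives** — the decoupled contrastive loss (positive pair excluded
  from the denominator; temperature 0.1; orthology pairs weighted 0.8),
  masked language modelling over 15% zeroed positions, and their
  α-weighted combination (α = 0.95).
* **Evaluation** — ridge / logistic linear probes on frozen embeddings with
  homology-aware splits and few-shot subsampling; Fisher-transformed,
  pooled Z-score ablation statistics with one-sided Welch top-tier tests;
  embedding similarity (1 − log L2), protein-domain and interval Jaccard
  analytics, isoform clustering with newick export, and exon-deletion
  embedding deltas.
* **Synthetic corpus** — a seeded generator of gene families with splice
  isoforms, substituted CDS-only orthologs, planted 3'UTR motifs that
  linearly determine a continuous label, functional classes and
  exon-derived domain annotations, written/read through the same standard
  formats as real data.

## Worked example

```r
library(rnaclr)

## a small synthetic corpus: 6 gene families, isoforms + 3 ortholog species
corpus <- simulateCorpus(simulationConfig(nFamilies = 6L, seed = 42L))
corpus
#> synthetic corpus: 6 families, 23 reference transcripts, 44 models total, 4 species

## augmentation sets: isoforms by gene, orthologs via the mapping table
isRef <- sapply(corpus$models, speciesId) == "ref"
sets <- buildSplicingSets(corpus$models[isRef])
sets <- buildOrthologySets(sets, corpus$mapping, corpus$models[!isRef],
                           corpus$rnas)
countPairs(sets)
#> 23 transcripts, 125 ordered positive pairs
#>   splicing: 56
#>   orthology: 69
#>   naive_orthology: 0

## one transcript: mature RNA and its six-track encoding
rna <- corpus$rnas[[1]]
rna
#> MatureRNA G0001-201: 936 nt (5'UTR 37 | CDS 693 | 3'UTR 206), 9 junction(s)
enc6 <- encodeSixTrack(rna, maxLen = 1536L)
enc6
#> SixTrackEncoding: 936 positions (936 valid), 9 junction(s), 231 codon start(s)

## a positive pair: orthology draws pass through the chimeric UTR
## transform and carry the reduced weight
pair <- samplePositivePair(transcriptId(rna), sets, corpus$rnas,
                           epoch = 1, seed = 7)
pair$source; pair$weight
#> [1] "orthology"
#> [1] 0.8

## the micro selective state-space encoder
encoder <- buildEncoder("selective", presetConfig("micro", maxLen = 1536L),
                        seed = 1)
encoder
#> RNAEncoder (selective): d_model 64, d_state 8, 2 layer(s), 41,252 parameters
out <- encodeSequence(encoder, enc6)
length(out$embedding)
#> [1] 64

## the decoupled contrastive loss on a hand-checkable batch: two
## orthogonal samples whose views coincide give log(2) - 1
dclLoss(rbind(c(1, 0), c(0, 1)), rbind(c(1, 0), c(0, 1)), temperature = 1)
#> [1] -0.3068528
```

`countPairs()` reports ordered reference→member pairs per augmentation
source; the pair above was an orthology draw, so its encoding is the
chimera of the reference's UTRs around the ortholog CDS and its positive
term is weighted 0.8. The embedding is the masked mean of the encoder's
per-position hidden states and has a fixed width (64 for the micro preset)
regardless of transcript length. Pre-training (`pretrain()`), probing
(`fitLinearProbe()`, `homologySplit()`), ablation statistics
(`aggregateZScores()`, `welchOneSided()`) and the similarity analytics
(`samplePairGroups()`, `similarityReport()`, `clusterIsoforms()`,
`exonDeletionDelta()`) are demonstrated end to end in
`tests/testthat/test-acceptance.R` and the methods vignette
(`vignettes/rnaclr-methods.Rmd`).

A thin command-line front end mirrors the pipeline
(`inst/cli/rnaclr simulate | build-pairs | pretrain | embed | probe |
ablate | similarity | cluster | exon-delta`), writing a JSON run manifest
(config snapshot, seed, input digests) into every output directory.

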