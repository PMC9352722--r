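# rloopscape

Genome-wide R-loop landscape analysis from DRIP-seq coverage, with HMM-based
peak calling, GC-skew gene classification, and integration with DNA
double-strand-break junction classes and replication timing.

## The problem

R-loops are three-stranded nucleic-acid structures — an RNA:DNA hybrid plus a
displaced single-stranded DNA — that form co-transcriptionally, preferentially
where the non-template strand is G-rich (positive GC skew). In neural
stem/progenitor cells under mild replication stress, recurrent DNA
double-strand breaks fall into two classes: junctions clustered around active
transcription start sites (TSSs), and recurrent DSB clusters (RDCs) in long,
late-replicating neural genes. This package provides the computational
machinery to map R-loops from DRIP-seq (DNA:RNA immunoprecipitation
sequencing) coverage and ask how they relate to those break classes,
transcription, promoter GC skew and replication timing.

## What's inside

* **Peak calling** — a two-state hidden Markov model on `log1p`-transformed
  binned coverage: Gaussian emissions per state, Baum–Welch fitting (EM, with
  guaranteed non-decreasing log-likelihood), Viterbi decoding with ties broken
  toward background, and run/merge/minimum-length post-processing
  (`callRloopPeaks()`).
* **GC-skew segmentation** — a four-state nucleotide-emission HMM over
  {no skew, strong, weak, reverse}; genes are assigned one of the four skew
  classes from the segments overlapping their promoter (TSS ± 2 kb), decoded
  on each gene's own non-template strand (`skewSegmentsGenome()`,
  `classifyGeneSkew()`).
* **Transcription classes** — per-gene GRO-seq RPKM
  (counts × 10⁹ / (length × library size)) with the three classes
  active (RPKM ≥ 0.025), ambiguous (0.0025 ≤ RPKM < 0.025) and inactive,
  plus transcription-rate-matched control sets (`expressionTable()`,
  `matchByTranscription()`).
* **Annotation** — single-label (midpoint) peak annotation against a
  prioritized genome partition (promoter > 5′UTR > 3′UTR > exon > TTS >
  intron > intergenic) with observed-vs-expected category fractions.
* **Integration** — junction-to-peak proximity within 2 kb windows,
  per-gene peak density, bp-weighted median replication timing,
  common/unique gene sets between conditions, metagene and TSS profiles,
  random peak down-sampling.
* **Statistics** — Mann–Whitney U (exact for small samples), one-way ANOVA
  with Tukey's post hoc test, accumulative hypergeometric gene-set enrichment
  with Benjamini–Hochberg q-values and kappa-similarity term clustering.
* **Synthetic data** — a deterministic 2 Mb toy-genome generator with planted
  ground truth (skewed promoters, transcription classes, R-loop peaks,
  junction classes, replication timing, enriched gene sets) so the whole
  pipeline is testable end to end without any external data.

All interval work uses Bioconductor containers (`GRanges`, `RleList`,
`DNAStringSet`); files are exchanged as BED, bedGraph, GTF, FASTA,
chrom.sizes and GMT.

## Worked example

```r
library(rloopscape)
res <- runPipeline("demo-run", seed = 1)
res$recovery
#>                   metric     value
#> 1 peak_recovery_fraction 1.0000000
#> 2    median_peak_jaccard 0.9323671
#> 3   skew_strong_recovery 1.0000000
#> 4     skew_none_recovery 1.0000000
#> 5  tss_junction_fraction 0.8500000
#> 6  rdc_junction_fraction 0.0450000
```

This simulates the default toy genome (2 Mb, 200 genes, 90 with GC-skewed
promoters, 10 long RDC-like genes), writes it to standard files, reads them
back, and runs every stage. With seed 1 the caller finds 199 peaks covering
7.79% of the toy genome; every planted peak is recovered (median Jaccard
0.93), every planted strong-skew and no-skew gene is classified correctly,
and the two junction classes separate sharply: 170/200 (85.00%) of TSS-class
junctions lie within 2 kb of an R-loop peak versus 9/200 (4.50%) of RDC-class
junctions — the qualitative signature that TSS-proximal breaks, but not RDC
breaks, sit in R-loop-rich, early-replicating chromatin (peak timing median
+1.5 vs −1.5 for RDC genes). `demo-run/report.md` tabulates the full summary
(class breakdowns, observed-vs-expected annotation, per-RDC-gene peak counts,
output hashes); each number is recomputable from the stage TSVs next to it.

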