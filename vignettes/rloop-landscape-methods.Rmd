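---
title: "Methods: R-loop landscape mapping, GC-skew classification and break-class integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: R-loop landscape mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the design decisions taken where the design was
genuinely open, and what the synthetic-data tests do and do not demonstrate
about real data.

## Scientific setting

R-loops form co-transcriptionally where the RNA re-anneals to the template
strand and displaces the G-rich non-template strand; promoter GC skew —
strand asymmetry (G−C)/(G+C) — predisposes a gene to R-loop formation.
DRIP-seq enriches RNA:DNA hybrids and yields a coverage track whose enriched
segments are R-loop peaks. In neural stem/progenitor cells under mild
replication stress, DNA double-strand-break junctions occur in two recurrent
classes: TSS-proximal junctions in short, highly transcribed genes, and
recurrent DSB clusters (RDCs) in long, late-replicating genes. The package's
integrative layer quantifies how R-loop peaks distribute over those classes,
over transcription and skew classes, and over replication timing.

## Coordinate and container conventions

All intervals are held as `GRanges` (1-based, closed, the Bioconductor
convention); BED and bedGraph files are 0-based half-open on disk and
converted at the file boundary in both directions, so round-trips are
bit-exact in the file's own convention. GTF is 1-based closed and imported
via `rtracklayer`. Coverage is a per-chromosome run-length-encoded vector
(`RleList`) spanning the full chromosome; unreported bedGraph positions
default to 0, or to `NA` (`fill = NA`) where "no data" must stay
distinguishable from "zero", as for replication-timing ratio tracks.
Chromosome names match by exact string equality; a mismatch is an error,
never a silent drop.

## Peak calling: two-state Gaussian HMM

Coverage is pooled across replicate tracks (position-wise sum; an alternative
k-of-n per-replicate intersection mode exists), averaged into fixed-width
bins, and transformed with `log1p`. A two-state HMM with Gaussian emissions —
state 1 background, state 2 enriched — is fitted by Baum–Welch, treating
chromosomes as independent sequences. Numerical choices:

* **Initialisation** from a quantile split: background moments from bins at
  or below the median, enriched moments from the top decile; initial
  transition matrix 0.9/0.1.
* **Stopping** at |Δ log-likelihood| < 1e-4 or 200 iterations; the
  log-likelihood trace is stored and is non-decreasing (an EM guarantee that
  the tests assert on every fitted input).
* **Guards**: emission standard deviations are floored at 1e-3 (no variance
  collapse); likelihoods are floored at 1e-300 before the scaled
  forward–backward pass; an all-constant input is rejected with advice to
  decode with fixed parameters instead.
* **Relabeling** after fitting so that state 2 always has the larger
  emission mean.
* **Viterbi ties** break toward background — calls are conservative.

Post-processing turns enriched-state runs into bp intervals: runs separated
by at most `merge_gap_bins` (default 1) background bins are merged, then
merged runs shorter than `min_bins` (default 3) are dropped. The function
default bin size is 500 bp, a common resolution for DRIP-seq on mammalian
genomes; the toy-genome pipeline default is 100 bp, matching the simulator's
~1:10 gene-length scale (below).

## GC-skew segmentation: four-state nucleotide HMM

The skew model has states NONE, STRONG, WEAK and REVERSE with per-state
emission distributions over A/C/G/T. The shipped parameter sets are declared
approximations chosen for their qualitative behaviour, and every number is
overridable:

* STRONG: P(G) = 0.40, P(C) = 0.20, P(A) = P(T) = 0.20;
* WEAK: P(G) = 0.30, P(C) = 0.20;
* NONE: uniform; REVERSE: the complement mirror of STRONG.
* Self-transition 1 − 1e-6 ("stringent", expected segment ~1 Mb; used for
  gene classification) or 1 − 1/7600 ("lenient", ~7.6 kb; suited to
  finer-grained metaplot work). Off-diagonal mass splits evenly.

Training the emissions from curated R-loop-forming regions is out of scope;
decoding uses fixed parameters. `N` bases emit with probability 1 under every
state (likelihood-neutral). Viterbi runs in log space; ties resolve to NONE
(the states are ordered with NONE first for exactly this reason).

**Strand handling.** Skew is defined on a gene's non-template (coding)
strand. Each chromosome is therefore decoded twice — as-is for plus-strand
genes, and as its reverse complement (segments mapped back to forward
coordinates) for minus-strand genes. This makes the decoding exactly
symmetric: decoding a reverse complement swaps STRONG and REVERSE and fixes
NONE (and WEAK, whenever WEAK's emissions are complement-symmetric), a
property the test suite checks directly.

**Gene classes.** A gene's class is the highest-priority state
(strong > weak > reverse > none) among segments overlapping its promoter
(TSS ± 2 kb) by at least 1 bp. Classes are promoter-anchored because
promoter skew is the feature tied to R-loop initiation at the TSS; a
whole-gene mode (`scope = "gene"`) is exposed for sensitivity analyses.

## Transcription classes and matching

GRO-seq measures nascent transcription, so expression is counted over the
full unspliced gene span. RPKM = counts × 10⁹ / (length × library size).
Class boundaries follow the inclusive-lower convention: active at
RPKM ≥ 0.025, ambiguous at 0.0025 ≤ RPKM < 0.025, inactive below. Two genes
are "similarly transcribed" when their RPKMs differ by at most 5% of the
larger value.

Building a transcription-matched control set is done greedily: targets in a
fixed internal order (descending RPKM, id tie-break), nearest available
candidate in log10(RPKM + 1e-6) without replacement, candidates inside the
±5% band preferred, and a hard cap of 0.5 log10 units beyond which a target
is dropped and reported. The exact matching algorithm was an open design
point; greedy nearest-neighbour was chosen for determinism and auditability,
and its audit is statistical: on a balanced candidate pool the matched and
target RPKM distributions are indistinguishable (Mann–Whitney p > 0.9 in the
test suite).

## Annotation

Feature categories are derived from the gene models (promoter = TSS ± 2 kb,
TTS = TES ± 1 kb, intron = span minus exons, UTRs only when the annotation
supplies them) and flattened into a genome partition using the fixed priority
promoter > 5′UTR > 3′UTR > exon > TTS > intron > intergenic — every bp
belongs to exactly one category, an invariant property-tested across random
gene sets. Peaks take the single label of their midpoint, which matches a
per-peak pie-chart reading of "genomic distribution of peaks"; expected
fractions are genome-bp fractions. The TTS half-width is a configurable
choice (1 kb) — no principled value is dictated by the data model.

## Break-class and timing integration

* A peak belongs to a gene when it overlaps the gene span extended upstream
  by the promoter window (so promoter peaks count); a body-only flag exists.
* A junction is R-loop-proximal when a peak overlaps the junction's ± 2 kb
  "breakpoint region"; equivalently, the peak's nearest edge is within
  2 kb of the junction position. Per-RDC-gene counts tally distinct peaks
  near any junction of the gene, not junction–peak pairs.
* Replication timing over an interval is the bp-weighted median of the ratio
  track (early > 0 > late), computed from run-length weights; at an exact
  half-weight boundary the two straddling values are averaged. Missing
  (unreported) timing is excluded, never zero-filled, and an interval with
  no timing data yields NA.
* Two-condition comparison reports common/unique gene sets with the common
  share of each side as a percentage; peak-number normalisation between
  conditions uses seeded uniform down-sampling without replacement.
* Metagene profiles use fixed-width flanks (2 kb in 20 bins) around a gene
  body rescaled to 100 bins by fractional-overlap averaging, strand-oriented
  so bin 1 is always 5′; genes shorter than the bin count are handled by the
  same fractional weights.

Percentages are printed at two decimals with round-half-even throughout.

## Enrichment statistics

Term enrichment uses the accumulative (upper-tail) hypergeometric
P(X ≥ k) with enrichment factor (k/n)/(K/N), Benjamini–Hochberg q-values,
and the standard filters: p < 0.01 (strict), overlap count ≥ 3, factor > 1.5
(strict). Surviving terms are clustered on pairwise Cohen's kappa computed
over binary gene-membership vectors on the union of surviving-term genes;
average-linkage hierarchical clustering is cut so terms joined at
kappa > 0.3 share a cluster, each represented by its smallest-p member.
Average linkage (rather than a maximum-similarity cut) was an open choice,
taken for its robustness to single-pair outliers. No ontology ships with the
package; gene sets come from user GMT files (the simulator writes a
synthetic one). The Mann–Whitney test is exact (no ties, combined n ≤ 12,
configurable) and otherwise uses the normal approximation with tie and
continuity corrections; ANOVA and Tukey's HSD are the classical fixed-effects
procedures.

## The synthetic-data generator

The simulator is first-class, tested code. It emulates the structure the
analyses rely on, with every stochastic draw taken from a single seeded
generator in documented order, so identical configurations give
byte-identical outputs.

Defaults (all in `simConfig()`), chosen once as a realistic toy version of a
mammalian neural-cell genome:

* 2 Mb over two chromosomes; 200 non-overlapping genes (log-normal lengths,
  median ~2.5 kb, clipped to 1–12 kb) with ≥ 4.5 kb intergenic gaps so
  promoter windows stay clear of neighbours. Gene lengths are ~1:10 of
  mammalian scale, which is why the long-gene (RDC-like) tail is 32–48 kb
  — the 300 kb-plus neural-gene scale reduced by the same factor — and why
  the toy pipeline bins coverage at 100 bp instead of the 500 bp function
  default.
* 45% of genes carry a skewed promoter: non-template-strand P(G) = 0.40,
  P(C) = 0.20 over TSS ± 2 kb plus the first quarter of the gene body
  (expected (G−C)/(G+C) = 1/3); the rest of the genome is i.i.d. uniform
  ACGT. Minus-strand genes are planted through the complement, so the skew
  sits on their coding strand.
* Transcription: 70/20/10% active/ambiguous/inactive, with planted RPKMs
  drawn inside each class's boundaries; the 40 shortest active genes become
  the TSS-junction class and get high RPKM (log-normal around 5). GRO
  coverage is uniform within genes at rpkm × library_size / 10⁹ reads per
  bp, so RPKM inverts exactly (library size 10⁶, declared in the manifest).
* R-loop peaks: skewed active genes get TSS, mid-body and TES peaks
  (600/600/500 bp; peaks closer than 600 bp merge into one planted
  interval); non-skewed active genes get the TES peak only; the 10 RDC-like
  genes get a single body peak with probability 0.2; ambiguous and inactive
  genes get none. DRIP coverage is Poisson per 10-bp step: background rate
  0.4, in-peak rate ×(1+SNR) with SNR 8.
* Junctions: 5 per TSS-class gene, uniform in TSS ± 2 kb; 20 per RDC gene,
  uniform in the body excluding TSS ± 2 kb.
* Timing: +1.5 over skewed-active genes ± 5 kb, −1.5 over RDC genes, 0
  elsewhere, written with explicit zero records so every position is
  reported.
* Gene sets: 15 random background terms of 30 genes plus 3 planted terms
  drawing 80% of their members from the skewed-active genes.

The monotone link between transcription and peak presence (peaks only in
active genes) is a modelling choice — no quantitative dose–response is
established for real data — and is deliberately simple.

**What the toy genome does not emulate.** Real mammalian genomes are ~98%
intergenic at this gene density's scale; the toy genome is ~50% genic with
70% of genes active, so planted peaks cover ~7% of the toy genome rather
than the ~1% seen genome-wide in real cells — the difference is intergenic
dilution, not peak biology, and the per-gene peak structure (TSS/body/TES
for skewed genes, TES-biased otherwise, sparse in RDC genes) is what the
recovery tests exercise. There is also no read-level simulation (coverage is
generated directly), no GC-content bias or mappability structure in the
noise, no replication-fork dynamics behind the timing track, and crisp
rather than graded timing domains. Passing the recovery criteria therefore
demonstrates correctness of the algorithms under their stated model, not
performance on real sequencing artefacts.

## Pipeline, determinism and problem sizes

`runPipeline()` executes simulate → write/read through the standard formats →
peak calling → skew classification → expression → annotation → integration →
enrichment → report, writing one TSV/BED per stage and a markdown report that
tabulates every figure-analog number and the md5 hash of every output. Two
runs with the same configuration produce identical hashes (tested). The test
and acceptance runs use the default 2 Mb / 200-gene configuration — sized so
a full end-to-end run, including two Viterbi decodes of the genome at 1 bp
resolution, completes in well under five minutes on a single core — which is
the package's chosen reference problem size.

## Known limitations

* The skew-model emissions and the peak-caller's structural defaults are
  declared approximations; on real data both should be examined against
  known R-loop-positive loci before interpretation.
* Strand-specific (DRIPc-style) calling, input-control modelling beyond
  optional subtraction, fragment-size effects and restriction-fragment
  resolution are out of scope.
* The greedy transcription matcher guarantees determinism, not global
  optimality of the matching.
* Junction calling itself (from translocation-sequencing reads) is upstream
  of this package; junction files are inputs.
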