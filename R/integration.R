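#' Promoter GC content
#'
#' Fractional (G+C)/(A+C+G+T) content over the promoter window TSS +/-
#' `halfwidth`, clipped to chromosome bounds; N bases are excluded from the
#' denominator. An all-N promoter is an error.
#'
#' @param gm A [GeneModels-class].
#' @param genome Named [Biostrings::DNAStringSet].
#' @param halfwidth Promoter half-width in bp.
#' @return Named numeric vector, one fraction per gene.
#' @export
promoterGC <- function(gm, genome, halfwidth = 2000L) {
  win <- promoterRegions(gm, halfwidth)
  out <- vapply(seq_along(win), function(i) {
    ch <- as.character(seqnames(win)[i])
    if (!ch %in% names(genome)) stop("chromosome not in genome: ", ch)
    L <- length(genome[[ch]])
    s <- max(1L, start(win)[i]); e <- min(end(win)[i], L)
    sub <- Biostrings::subseq(genome[[ch]], s, e)
    f <- Biostrings::letterFrequency(sub, c("A", "C", "G", "T"))
    denom <- sum(f)
    if (denom == 0) stop("all-N promoter for gene ",
                         mcols(win)$gene_id[i])
    as.numeric((f[["C"]] + f[["G"]]) / denom)
  }, 0)
  stats::setNames(out, mcols(win)$gene_id)
}

.extended_spans <- function(gm, promoterHalfwidth, bodyOnly = FALSE) {
  g <- geneRanges(gm)
  if (!bodyOnly) {
    plus <- as.character(strand(g)) == "+"
    start(g)[plus] <- pmax(1L, start(g)[plus] - promoterHalfwidth)
    end(g)[!plus] <- end(g)[!plus] + promoterHalfwidth
    sl <- seqlengths(g)
    if (!any(is.na(sl)))
      end(g) <- pmin(end(g), sl[as.character(seqnames(g))])
  }
  g
}

#' Assign peaks to genes
#'
#' A peak is assigned to every gene whose span, extended upstream by the
#' promoter window (so promoter peaks count), it overlaps by at least 1 bp. A
#' peak overlapping several genes serves all of them.
#'
#' @param peaks A `GRanges`.
#' @param gm A [GeneModels-class].
#' @param promoterHalfwidth Promoter half-width in bp.
#' @param bodyOnly Restrict to the gene body (no promoter extension).
#' @return Named list (per gene id) of integer indices into `peaks`; genes
#'   without peaks get an empty vector.
#' @export
assignPeaksToGenes <- function(peaks, gm, promoterHalfwidth = 2000L,
                               bodyOnly = FALSE) {
  ext <- .extended_spans(gm, promoterHalfwidth, bodyOnly)
  hits <- findOverlaps(ext, peaks, minoverlap = 1L, ignore.strand = TRUE)
  out <- split(S4Vectors::subjectHits(hits),
               factor(S4Vectors::queryHits(hits), levels = seq_along(ext)))
  names(out) <- geneIds(gm)
  lapply(out, function(x) sort(as.integer(x)))
}

#' Gene-length-normalized peak density
#'
#' @param peakCount Number of peaks assigned to the gene(s).
#' @param lengthBp Gene length(s) in bp (> 0).
#' @return Peaks per kb (vectorized).
#' @export
peakDensity <- function(peakCount, lengthBp) {
  if (any(lengthBp <= 0)) stop("gene length must be > 0")
  peakCount / (lengthBp / 1000)
}

#' Junction-to-peak proximity
#'
#' A breakpoint junction counts as R-loop-associated when at least one peak
#' lies within `window` bp of it (the junction's +/- `window` "breakpoint
#' region" overlaps the peak). A peak whose nearest edge is more than `window`
#' bp away does not count.
#'
#' @param junctions Non-empty `GRanges` of junction positions.
#' @param peaks `GRanges` of peaks.
#' @param window Proximity window in bp (>= 0).
#' @return List: `n_within`, `n_total`, `fraction`, and `percent` (two
#'   decimals, round-half-even).
#' @export
junctionPeakProximity <- function(junctions, peaks, window = 2000L) {
  if (length(junctions) == 0L) stop("empty junction set")
  if (window < 0) stop("window must be >= 0")
  reg <- junctions
  start(reg) <- pmax(1L, start(reg) - window)
  end(reg) <- end(reg) + window
  nWithin <- sum(countOverlaps(reg, peaks, ignore.strand = TRUE) > 0)
  frac <- nWithin / length(junctions)
  list(n_within = as.integer(nWithin), n_total = length(junctions),
       fraction = frac, percent = round(100 * frac, 2))
}

#' Peaks near junctions, per gene
#'
#' For each gene, the number of distinct peaks with at least one of the gene's
#' junctions within `window` bp (counting peaks, not junction-peak pairs).
#'
#' @param peaks `GRanges` of peaks.
#' @param junctions `GRanges` with a `gene_id` metadata column labelling each
#'   junction's gene.
#' @param geneIds Character vector of gene ids to report (genes without
#'   junctions or peaks report 0).
#' @param window Proximity window in bp.
#' @return Named integer vector.
#' @export
peaksNearJunctionsPerGene <- function(peaks, junctions, geneIds,
                                      window = 2000L) {
  if (is.null(mcols(junctions)$gene_id))
    stop("junctions need a gene_id column")
  reg <- junctions
  start(reg) <- pmax(1L, start(reg) - window)
  end(reg) <- end(reg) + window
  hits <- findOverlaps(reg, peaks, ignore.strand = TRUE)
  gid <- mcols(junctions)$gene_id[S4Vectors::queryHits(hits)]
  pk <- S4Vectors::subjectHits(hits)
  counts <- vapply(split(pk, factor(gid, levels = geneIds)),
                   function(x) length(unique(x)), 0L)
  stats::setNames(as.integer(counts), geneIds)
}

.weighted_median <- function(values, weights) {
  keep <- !is.na(values) & weights > 0
  v <- values[keep]; w <- weights[keep]
  if (length(v) == 0L) return(NA_real_)
  o <- order(v)
  v <- v[o]; w <- w[o]
  cw <- cumsum(w)
  half <- sum(w) / 2
  i <- which(cw >= half)[1]
  if (isTRUE(all.equal(cw[i], half)) && i < length(v)) (v[i] + v[i + 1]) / 2
  else v[i]
}

#' Median replication timing over intervals
#'
#' bp-weighted median of a replication-timing ratio track over each interval.
#' Positions with no timing record (NA in the track) are excluded; an interval
#' with no reported timing yields NA (and a message).
#'
#' @param intervals A `GRanges`.
#' @param timing An `RleList` ratio track (read with `fill = NA` to keep
#'   unreported regions distinguishable; early > 0 > late).
#' @return Numeric vector of medians (NA where undefined).
#' @export
intervalTiming <- function(intervals, timing) {
  out <- vapply(seq_along(intervals), function(i) {
    ch <- as.character(seqnames(intervals)[i])
    if (!ch %in% names(timing)) stop("chromosome not in timing track: ", ch)
    r <- timing[[ch]]
    s <- max(1L, start(intervals)[i]); e <- min(end(intervals)[i], length(r))
    if (s > e) return(NA_real_)
    v <- Views(r, start = s, end = e)[[1]]
    .weighted_median(runValue(v), runLength(v))
  }, 0)
  if (anyNA(out))
    message(sum(is.na(out)), " interval(s) without timing coverage: ",
            "reported as NA and excluded downstream")
  out
}

#' Common and unique gene sets between two conditions
#'
#' Venn arithmetic for genes with R-loop peaks in two cell types: common =
#' intersection, unique sets = set differences, with the common share of each
#' side reported as a percentage at two decimals (round-half-even).
#'
#' @param genesA,genesB Character vectors of gene ids.
#' @return List: `common`, `unique_a`, `unique_b`, `pct_common_of_a`,
#'   `pct_common_of_b`.
#' @export
commonUniqueGeneSets <- function(genesA, genesB) {
  genesA <- unique(genesA); genesB <- unique(genesB)
  common <- intersect(genesA, genesB)
  list(common = common,
       unique_a = setdiff(genesA, genesB),
       unique_b = setdiff(genesB, genesA),
       pct_common_of_a = if (length(genesA))
         round(100 * length(common) / length(genesA), 2) else NA_real_,
       pct_common_of_b = if (length(genesB))
         round(100 * length(common) / length(genesB), 2) else NA_real_)
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Random down-sampling of a peak set
#'
#' Uniform sample of exactly `k` peaks without replacement, deterministic
#' given the seed (used e.g. to equalize peak numbers between cell types
#' before comparison).
#'
#' @param peaks A `GRanges`.
#' @param k Target size, 0 <= k <= length(peaks).
#' @param seed Integer seed.
#' @return A `GRanges` of `k` peaks (sorted).
#' @export
downsamplePeaks <- function(peaks, k, seed = 1L) {
  if (k < 0 || k > length(peaks))
    stop("k must be between 0 and the number of peaks")
  idx <- .with_seed(seed, sample(seq_along(peaks), k))
  sort(peaks[idx])
}

.pad_values <- function(r, s, e) {
  # per-bp values over [s, e] with NA outside [1, length(r)]
  L <- length(r)
  lo <- max(1L, s); hi <- min(e, L)
  core <- if (lo <= hi) as.numeric(Views(r, start = lo, end = hi)[[1]])
          else numeric(0)
  c(rep(NA_real_, lo - s), core, rep(NA_real_, e - hi))
}

.rescale_bins <- function(v, nbins) {
  L <- length(v)
  bounds <- (0:nbins) * L / nbins
  out <- numeric(nbins)
  for (b in seq_len(nbins)) {
    lo <- bounds[b]; hi <- bounds[b + 1]
    i0 <- floor(lo) + 1L; i1 <- min(ceiling(hi), L)
    idx <- i0:i1
    w <- pmin(hi, idx) - pmax(lo, idx - 1)
    w[w < 0] <- 0
    vv <- v[idx]
    ok <- !is.na(vv) & w > 0
    out[b] <- if (any(ok)) sum(vv[ok] * w[ok]) / sum(w[ok]) else NA_real_
  }
  out
}

.gene_profile <- function(track, gm, i, bodyBins, flankBp, flankBins) {
  g <- geneRanges(gm)[i]
  ch <- as.character(seqnames(g))
  r <- track[[ch]]
  if (is.null(r)) stop("chromosome not in track: ", ch)
  v <- .pad_values(r, start(g) - flankBp, end(g) + flankBp)
  if (as.character(strand(g)) == "-") v <- rev(v)
  up <- v[seq_len(flankBp)]
  body <- v[(flankBp + 1):(length(v) - flankBp)]
  down <- v[(length(v) - flankBp + 1):length(v)]
  c(.rescale_bins(up, flankBins), .rescale_bins(body, bodyBins),
    .rescale_bins(down, flankBins))
}

#' Metagene coverage profile
#'
#' Strand-oriented composite profile over genes: fixed-width upstream flank,
#' gene body rescaled to `bodyBins`, fixed-width downstream flank; minus-strand
#' genes are reversed so bin 1 is always 5'. Genes shorter than `bodyBins` bp
#' are rescaled by fractional overlap. The profile is the per-bin mean across
#' genes.
#'
#' @param track An `RleList` coverage track.
#' @param gm A [GeneModels-class].
#' @param bodyBins Number of gene-body bins.
#' @param flankBp Flank width in bp.
#' @param flankBins Number of bins per flank.
#' @return Numeric vector of length `2 * flankBins + bodyBins`.
#' @export
metageneProfile <- function(track, gm, bodyBins = 100L, flankBp = 2000L,
                            flankBins = 20L) {
  if (length(gm) == 0L) stop("no genes")
  mat <- vapply(seq_len(length(gm)), function(i)
    .gene_profile(track, gm, i, bodyBins, flankBp, flankBins),
    numeric(2L * flankBins + bodyBins))
  rowMeans(mat, na.rm = TRUE)
}

#' TSS-centred coverage profile
#'
#' Mean strand-oriented coverage in fixed bins over TSS +/- `flankBp`.
#'
#' @param track An `RleList` coverage track.
#' @param gm A [GeneModels-class].
#' @param flankBp Flank in bp on each side of the TSS.
#' @param bin Bin width in bp (must divide `2 * flankBp`).
#' @return Numeric vector of length `2 * flankBp / bin`.
#' @export
tssProfile <- function(track, gm, flankBp = 2000L, bin = 50L) {
  if ((2L * flankBp) %% bin != 0L) stop("bin must divide 2 * flankBp")
  nb <- 2L * flankBp / bin
  t0 <- tss(gm)
  mat <- vapply(seq_along(t0), function(i) {
    ch <- as.character(seqnames(t0)[i])
    r <- track[[ch]]
    if (is.null(r)) stop("chromosome not in track: ", ch)
    minus <- as.character(strand(t0)[i]) == "-"
    # window covers flankBp on each side of the TSS, oriented 5' -> 3'
    v <- if (minus)
      rev(.pad_values(r, start(t0)[i] - flankBp + 1L, start(t0)[i] + flankBp))
    else .pad_values(r, start(t0)[i] - flankBp, start(t0)[i] + flankBp - 1L)
    colMeans(matrix(v, nrow = bin), na.rm = TRUE)
  }, numeric(nb))
  rowMeans(mat, na.rm = TRUE)
}

#' Per-gene statistics table
#'
#' Assembles the per-gene summary used throughout the integrative analyses:
#' length, GRO-seq RPKM and transcription class, GC-skew class, assigned peak
#' count and length-normalized density, promoter GC fraction, bp-weighted
#' median replication timing over the gene span, and junction flags.
#'
#' @param gm A [GeneModels-class].
#' @param peaks `GRanges` of R-loop peaks.
#' @param expr Expression table from [expressionTable].
#' @param skewClasses Named skew classes from [classifyGeneSkew] (optional).
#' @param genome Optional `DNAStringSet` for promoter GC.
#' @param timing Optional timing `RleList`.
#' @param tssJunctions,rdcJunctions Optional junction `GRanges`; TSS-class
#'   junctions flag genes via overlap with the promoter window, RDC-class
#'   junctions must carry `gene_id`.
#' @param config An [analysisConfig].
#' @return data.frame with one row per gene.
#' @export
geneStatsTable <- function(gm, peaks, expr, skewClasses = NULL, genome = NULL,
                           timing = NULL, tssJunctions = NULL,
                           rdcJunctions = NULL, config = analysisConfig()) {
  ids <- geneIds(gm)
  assign <- assignPeaksToGenes(peaks, gm, config$promoter_halfwidth)
  nPeaks <- lengths(assign)[ids]
  df <- data.frame(gene_id = ids, length = width(geneRanges(gm)),
                   stringsAsFactors = FALSE)
  ex <- expr[match(ids, expr$gene_id), ]
  df$rpkm <- ex$rpkm
  df$transcription_class <- ex$class
  df$skew_class <- if (is.null(skewClasses)) NA_character_
                   else unname(skewClasses[ids])
  df$peak_count <- as.integer(nPeaks)
  df$peak_density <- peakDensity(nPeaks, df$length)
  df$promoter_gc <- if (is.null(genome)) NA_real_
                    else unname(promoterGC(gm, genome,
                                           config$promoter_halfwidth))
  df$median_timing <- if (is.null(timing)) NA_real_
                      else suppressMessages(
                        intervalTiming(geneRanges(gm), timing))
  df$has_tss_junction <- if (is.null(tssJunctions)) NA else
    countOverlaps(promoterRegions(gm, config$promoter_halfwidth),
                  tssJunctions, ignore.strand = TRUE) > 0
  df$is_rdc <- if (is.null(rdcJunctions)) NA else
    ids %in% unique(mcols(rdcJunctions)$gene_id)
  df
}
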