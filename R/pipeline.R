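#' Planted-peak recovery
#'
#' For every planted peak, the best Jaccard index (intersection over union,
#' in bp) against the called peak set; a planted peak counts as recovered at
#' Jaccard >= `minJaccard`.
#'
#' @param planted,called `GRanges` peak sets.
#' @param minJaccard Recovery threshold.
#' @return List: `fraction_recovered`, `jaccard` (per planted peak),
#'   `n_planted`, `n_called`.
#' @export
peakRecovery <- function(planted, called, minJaccard = 0.5) {
  if (length(planted) == 0L) stop("no planted peaks")
  jac <- vapply(seq_along(planted), function(i) {
    p <- planted[i]
    hits <- findOverlaps(p, called, ignore.strand = TRUE)
    if (length(hits) == 0L) return(0)
    max(vapply(S4Vectors::subjectHits(hits), function(j) {
      q <- called[j]
      inter <- min(end(p), end(q)) - max(start(p), start(q)) + 1
      uni <- max(end(p), end(q)) - min(start(p), start(q)) + 1
      inter / uni
    }, 0))
  }, 0)
  list(fraction_recovered = mean(jac >= minJaccard), jaccard = jac,
       n_planted = length(planted), n_called = length(called))
}

#' Skew-class label recovery
#'
#' Compares decoded gene skew classes against planted labels for the two
#' planted classes (strong-skew and no-skew genes).
#'
#' @param classes Named classes from [classifyGeneSkew].
#' @param groundTruth Simulation ground-truth data.frame (needs `gene_id`,
#'   `skew_class_planted`).
#' @return List: `strong_recovery`, `none_recovery` (fractions).
#' @export
skewClassRecovery <- function(classes, groundTruth) {
  planted <- stats::setNames(groundTruth$skew_class_planted,
                             groundTruth$gene_id)
  cl <- classes[names(planted)]
  list(strong_recovery = mean(cl[planted == "strong"] == "strong"),
       none_recovery = mean(cl[planted == "none"] == "none"))
}

.write_tsv <- function(df, path) {
  df <- df[, !vapply(df, is.list, TRUE), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Orchestrates every stage in order: simulate, write the simulation to
#' standard files and read it back through the package's own readers, call
#' R-loop peaks from the DRIP track, decode GC skew and classify genes,
#' compute the GRO-seq expression table, annotate peaks, assemble the
#' integrative gene-statistics table, junction-proximity and timing analyses,
#' a called-vs-planted gene-set comparison, gene-set enrichment with term
#' clustering, ground-truth recovery metrics, and a human-readable report.
#' Output files are hashed in the report; a rerun with an identical
#' configuration reproduces identical hashes.
#'
#' @param outDir Output directory.
#' @param simCfg A [simConfig].
#' @param config An [analysisConfig]; the default uses 100-bp peak-caller bins
#'   matching the toy genome's ~1:10 gene-length scale (see the package
#'   vignette), while [callRloopPeaks]'s own default stays 500 bp.
#' @param seed Overrides both configs' seeds when not `NULL`.
#' @return Invisibly, a list with all stage results (`sim`, `peaks`,
#'   `skew_classes`, `expr`, `annotation`, `gene_stats`, `proximity_tss`,
#'   `proximity_rdc`, `timing_summary`, `venn`, `enrichment`, `clusters`,
#'   `recovery`, `report_path`, `files`).
#' @export
runPipeline <- function(outDir, simCfg = simConfig(),
                        config = analysisConfig(bin_size = 100L),
                        seed = NULL) {
  if (!is.null(seed)) {
    simCfg$seed <- as.integer(seed)
    config$seed <- as.integer(seed)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  # -- simulate and round-trip through the standard formats
  sim <- simulateRloopData(simCfg)
  files <- writeSimulation(sim, file.path(outDir, "sim"))
  chromSizes <- readChromSizes(files[["chrom_sizes"]])
  genome <- readGenomeFasta(files[["fasta"]], chromSizes)
  gm <- readGtfGenes(files[["gtf"]], chromSizes)
  drip <- readBedGraph(files[["drip"]], chromSizes)
  gro <- readBedGraph(files[["gro"]], chromSizes)
  timing <- readBedGraph(files[["timing"]], chromSizes, fill = NA,
                         allowNegative = TRUE)
  juncTss <- readBed(files[["junctions_tss"]], chromSizes)
  mcols(juncTss)$gene_id <- mcols(juncTss)$name
  juncRdc <- readBed(files[["junctions_rdc"]], chromSizes)
  mcols(juncRdc)$gene_id <- mcols(juncRdc)$name
  planted <- readBed(files[["peaks"]], chromSizes)
  geneSets <- readGmt(files[["gmt"]])

  # -- peak calling
  peaks <- callRloopPeaks(drip, chromSizes, binSize = config$bin_size,
                          minBins = config$min_bins,
                          mergeGapBins = config$merge_gap_bins)
  writeBed(peaks, file.path(outDir, "peaks.bed"))

  # -- GC skew
  segs <- skewSegmentsGenome(genome, skewHmm("stringent"))
  skewClasses <- classifyGeneSkew(gm, segs, config$promoter_halfwidth)
  .write_tsv(data.frame(gene_id = names(skewClasses),
                        skew_class = unname(skewClasses)),
             file.path(outDir, "skew_classes.tsv"))

  # -- expression
  expr <- expressionTable(gm, gro, librarySize = simCfg$library_size,
                          config = config)
  .write_tsv(expr, file.path(outDir, "expression.tsv"))

  # -- annotation
  annot <- buildAnnotation(gm, chromSizes, config$promoter_halfwidth,
                           config$tts_halfwidth)
  ove <- observedVsExpected(peaks, annot)
  .write_tsv(ove, file.path(outDir, "annotation.tsv"))

  # -- integration
  stats <- geneStatsTable(gm, peaks, expr, skewClasses, genome, timing,
                          juncTss, juncRdc, config)
  .write_tsv(stats, file.path(outDir, "gene_stats.tsv"))
  proxTss <- junctionPeakProximity(juncTss, peaks, config$junction_window)
  proxRdc <- junctionPeakProximity(juncRdc, peaks, config$junction_window)
  rdcIds <- sort(unique(mcols(juncRdc)$gene_id))
  rdcPeakCounts <- peaksNearJunctionsPerGene(peaks, juncRdc, rdcIds,
                                             config$junction_window)
  .write_tsv(data.frame(class = c("TSS", "RDC"),
                        n_within = c(proxTss$n_within, proxRdc$n_within),
                        n_total = c(proxTss$n_total, proxRdc$n_total),
                        percent = c(proxTss$percent, proxRdc$percent)),
             file.path(outDir, "junction_proximity.tsv"))
  .write_tsv(data.frame(gene_id = rdcIds,
                        peaks_near_junctions = as.integer(rdcPeakCounts)),
             file.path(outDir, "rdc_peak_counts.tsv"))

  # -- replication timing of peaks
  gt <- sim$ground_truth
  peakTiming <- suppressMessages(intervalTiming(peaks, timing))
  earlyGenes <- gt$gene_id[gt$skewed & gt$transcription_class == "active"]
  assign <- assignPeaksToGenes(peaks, gm, config$promoter_halfwidth)
  earlyPeakIdx <- unique(unlist(assign[earlyGenes], use.names = FALSE))
  rdcTiming <- stats$median_timing[stats$gene_id %in% rdcIds]
  timingSummary <- list(
    all_peaks_median = stats::median(peakTiming, na.rm = TRUE),
    early_peaks_median = stats::median(peakTiming[earlyPeakIdx], na.rm = TRUE),
    rdc_genes_median = stats::median(rdcTiming, na.rm = TRUE))

  # -- called-vs-planted gene sets (Venn arithmetic check of the run)
  calledGenes <- names(assign)[lengths(assign) > 0]
  plantedGenes <- geneIds(gm)[countOverlaps(
    .extended_spans(gm, config$promoter_halfwidth), planted,
    ignore.strand = TRUE) > 0]
  venn <- commonUniqueGeneSets(calledGenes, plantedGenes)

  # -- enrichment on skewed active genes with peaks
  query <- intersect(earlyGenes, calledGenes)
  enr <- enrichGeneSets(query, geneSets, geneIds(gm))
  clusters <- filterAndClusterTerms(enr)
  .write_tsv(enr[order(enr$p_value), ], file.path(outDir, "enrichment.tsv"))
  .write_tsv(clusters, file.path(outDir, "enrichment_clusters.tsv"))

  # -- ground-truth recovery
  rec <- peakRecovery(planted, peaks)
  skewRec <- skewClassRecovery(skewClasses, gt)
  recovery <- data.frame(
    metric = c("peak_recovery_fraction", "median_peak_jaccard",
               "skew_strong_recovery", "skew_none_recovery",
               "tss_junction_fraction", "rdc_junction_fraction"),
    value = c(rec$fraction_recovered, stats::median(rec$jaccard),
              skewRec$strong_recovery, skewRec$none_recovery,
              proxTss$fraction, proxRdc$fraction))
  .write_tsv(recovery, file.path(outDir, "recovery.tsv"))

  res <- list(sim = sim, peaks = peaks, skew_classes = skewClasses,
              expr = expr, annotation = ove, gene_stats = stats,
              proximity_tss = proxTss, proximity_rdc = proxRdc,
              rdc_peak_counts = rdcPeakCounts, peak_timing = peakTiming,
              timing_summary = timingSummary, venn = venn, enrichment = enr,
              clusters = clusters, recovery = recovery, files = files,
              chrom_sizes = chromSizes)
  res$report_path <- pipelineReport(outDir, res)
  invisible(res)
}

.fmt_pct <- function(x) sprintf("%.2f", round(100 * x, 2))

#' Render the pipeline report
#'
#' Writes a markdown summary of a pipeline run: peak count and genome
#' coverage, transcription-class and skew-class breakdowns of genes with
#' peaks, the observed/expected annotation table, junction-proximity
#' fractions, per-RDC-gene peak counts, timing medians per group, the
#' called-vs-planted Venn with its arithmetic identity, and md5 hashes of the
#' stage outputs. All percentages are printed at two decimals
#' (round-half-even).
#'
#' @param outDir The pipeline output directory.
#' @param res The result list of [runPipeline] (when omitted, the stage TSVs
#'   in `outDir` are not re-parsed; the report requires `res`).
#' @return The report path, invisibly.
#' @export
pipelineReport <- function(outDir, res) {
  gt <- res$sim$ground_truth
  stats <- res$gene_stats
  withPeaks <- stats[stats$peak_count > 0, ]
  covPct <- .fmt_pct(genomeCoverageFraction(res$peaks, res$chrom_sizes))
  L <- c("# R-loop landscape pipeline report", "",
         "## Peaks",
         sprintf("- R-loop peaks called: %d", length(res$peaks)),
         sprintf("- Genome covered by peaks: %s%%", covPct),
         sprintf("- Genes with >= 1 peak: %d of %d", nrow(withPeaks),
                 nrow(stats)), "",
         "## Transcription classes of genes with peaks")
  tc <- table(factor(withPeaks$transcription_class,
                     c("active", "ambiguous", "inactive")))
  L <- c(L, sprintf("- %s: %d (%s%%)", names(tc), as.integer(tc),
                    .fmt_pct(as.integer(tc) / max(1, sum(tc)))), "",
         "## GC-skew classes of genes with peaks")
  sc <- table(factor(withPeaks$skew_class,
                     c("strong", "weak", "none", "reverse")))
  L <- c(L, sprintf("- %s: %d (%s%%)", names(sc), as.integer(sc),
                    .fmt_pct(as.integer(sc) / max(1, sum(sc)))), "",
         "## Peak annotation (observed vs expected fraction)")
  a <- res$annotation
  L <- c(L, sprintf("- %s: %s%% observed vs %s%% expected", a$category,
                    .fmt_pct(a$observed), .fmt_pct(a$expected)), "",
         "## Junction proximity (peak within 2 kb)",
         sprintf("- TSS-class junctions: %d/%d (%s%%)",
                 res$proximity_tss$n_within, res$proximity_tss$n_total,
                 .fmt_pct(res$proximity_tss$fraction)),
         sprintf("- RDC-class junctions: %d/%d (%s%%)",
                 res$proximity_rdc$n_within, res$proximity_rdc$n_total,
                 .fmt_pct(res$proximity_rdc$fraction)), "",
         "## Peaks near junctions per RDC-gene")
  L <- c(L, sprintf("- %s: %d", names(res$rdc_peak_counts),
                    as.integer(res$rdc_peak_counts)), "",
         "## Replication timing (median ratio)",
         sprintf("- all peaks: %.3f", res$timing_summary$all_peaks_median),
         sprintf("- peaks in skewed active genes: %.3f",
                 res$timing_summary$early_peaks_median),
         sprintf("- RDC-like genes: %.3f",
                 res$timing_summary$rdc_genes_median), "",
         "## Called vs planted gene sets")
  v <- res$venn
  nA <- length(v$common) + length(v$unique_a)
  nB <- length(v$common) + length(v$unique_b)
  L <- c(L, sprintf("- common: %d; unique to called: %d; unique to planted: %d",
                    length(v$common), length(v$unique_a), length(v$unique_b)),
         sprintf("- common share: %.2f%% of called, %.2f%% of planted",
                 v$pct_common_of_a, v$pct_common_of_b),
         sprintf("- Venn identity |common|+|unique| = |set|: %s / %s",
                 nA == length(unique(c(v$common, v$unique_a))),
                 nB == length(unique(c(v$common, v$unique_b)))), "",
         "## Ground-truth recovery")
  L <- c(L, sprintf("- %s: %.4f", res$recovery$metric, res$recovery$value), "",
         "## Output hashes")
  outs <- sort(list.files(outDir, pattern = "\\.(tsv|bed|bedGraph)$",
                          recursive = TRUE, full.names = TRUE))
  h <- tools::md5sum(outs)
  L <- c(L, sprintf("- %s: %s", sub(paste0("^", outDir, "/?"), "", outs),
                    unname(h)))
  path <- file.path(outDir, "report.md")
  writeLines(L, path)
  invisible(path)
}
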