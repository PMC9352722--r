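#' Simulation configuration
#'
#' Parameters of the synthetic R-loop genome. Defaults define a 2 Mb toy
#' genome over two chromosomes with 200 non-overlapping genes; 45 percent of
#' genes carry a GC-skewed promoter (non-template-strand P(G) = 0.40, P(C) =
#' 0.20 over TSS +/- 2 kb and the first quarter of the gene body); gene
#' lengths are log-normal with a long-gene tail of `n_rdc_genes` recurrent-
#' break-cluster-like genes (> 30 kb, the 300 kb neural-gene scale reduced
#' with the 1:10 gene-length scaling of the toy genome); transcription is
#' planted in three classes (70/20/10 percent active/ambiguous/inactive);
#' DRIP-seq coverage is Poisson per 10-bp step at `drip_snr`-fold enrichment
#' over background inside planted peaks; junction classes, a +/-1.5
#' early/late replication-timing track and synthetic gene sets (GMT) with
#' planted enriched terms complete the ground truth.
#'
#' @param genome_size,n_chroms Total genome size in bp and chromosome count.
#' @param n_genes Number of genes (including RDC-like genes).
#' @param fraction_skewed_promoters Fraction of genes with skewed promoters.
#' @param gene_length_meanlog,gene_length_sdlog,gene_length_min,gene_length_max
#'   Log-normal gene-length distribution (bp), clipped.
#' @param n_rdc_genes,rdc_length_min,rdc_length_max Long-gene tail.
#' @param n_tss_junction_genes Short, highly transcribed genes that receive
#'   TSS-proximal junctions.
#' @param frac_active,frac_ambiguous Transcription-class fractions (inactive
#'   is the remainder).
#' @param active_rpkm_meanlog,active_rpkm_sdlog Log-normal RPKM for active
#'   genes.
#' @param tss_gene_rpkm_meanlog RPKM location for the highly transcribed
#'   TSS-junction genes.
#' @param library_size Declared GRO-seq library size (total mapped reads).
#' @param drip_step,drip_background,drip_snr Poisson noise model: step size in
#'   bp, background rate per step, signal-to-noise ratio (peak rate =
#'   background x (1 + snr)).
#' @param peak_width_tss,peak_width_body,peak_width_tes Planted peak widths.
#' @param peak_min_gap Planted peaks closer than this merge into one.
#' @param rdc_peak_prob Probability an RDC-like gene carries a (single, body)
#'   peak.
#' @param n_junctions_per_tss_gene,n_junctions_per_rdc_gene Junction counts.
#' @param skew_g_prob,skew_c_prob Non-template-strand G/C probabilities in
#'   skewed windows.
#' @param skew_body_fraction Fraction of the gene body (from the TSS) included
#'   in the skewed window.
#' @param promoter_halfwidth Promoter half-width in bp.
#' @param min_gene_gap Minimum intergenic gap in bp.
#' @param timing_early,timing_late,timing_flank Replication-timing plateau
#'   values and the flank (bp) around early genes.
#' @param n_terms,n_planted_terms,term_size,planted_term_purity Synthetic
#'   gene-set collection: number of background terms, planted (truly
#'   enriched) terms, genes per term, and the fraction of a planted term
#'   drawn from skewed active genes.
#' @param seed Single global seed; all draws come from one generator in
#'   documented order, so identical configs give byte-identical outputs.
#' @return A classed list.
#' @export
simConfig <- function(genome_size = 2e6, n_chroms = 2L, n_genes = 200L,
                      fraction_skewed_promoters = 0.45,
                      gene_length_meanlog = log(2500),
                      gene_length_sdlog = 0.55,
                      gene_length_min = 1000L, gene_length_max = 12000L,
                      n_rdc_genes = 10L, rdc_length_min = 32000L,
                      rdc_length_max = 48000L,
                      n_tss_junction_genes = 40L,
                      frac_active = 0.70, frac_ambiguous = 0.20,
                      active_rpkm_meanlog = log(1), active_rpkm_sdlog = 1,
                      tss_gene_rpkm_meanlog = log(5),
                      library_size = 1e6,
                      drip_step = 10L, drip_background = 0.4, drip_snr = 8,
                      peak_width_tss = 600L, peak_width_body = 600L,
                      peak_width_tes = 500L, peak_min_gap = 600L,
                      rdc_peak_prob = 0.2,
                      n_junctions_per_tss_gene = 5L,
                      n_junctions_per_rdc_gene = 20L,
                      skew_g_prob = 0.40, skew_c_prob = 0.20,
                      skew_body_fraction = 0.25,
                      promoter_halfwidth = 2000L,
                      min_gene_gap = 4500L,
                      timing_early = 1.5, timing_late = -1.5,
                      timing_flank = 5000L,
                      n_terms = 15L, n_planted_terms = 3L, term_size = 30L,
                      planted_term_purity = 0.8,
                      seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$genome_size > 0, cfg$n_chroms >= 1, cfg$n_genes > 0,
            cfg$fraction_skewed_promoters >= 0,
            cfg$fraction_skewed_promoters <= 1,
            cfg$frac_active + cfg$frac_ambiguous <= 1,
            cfg$n_rdc_genes >= 0, cfg$n_rdc_genes < cfg$n_genes,
            cfg$drip_snr >= 0, cfg$drip_background > 0)
  structure(cfg, class = "SimConfig")
}

# ---- internal generation stages (all draw from the ambient RNG stream) ----

.sim_gene_layout <- function(cfg) {
  nReg <- cfg$n_genes - cfg$n_rdc_genes
  lenReg <- pmin(pmax(round(stats::rlnorm(nReg, cfg$gene_length_meanlog,
                                          cfg$gene_length_sdlog)),
                      cfg$gene_length_min), cfg$gene_length_max)
  lenRdc <- round(stats::runif(cfg$n_rdc_genes, cfg$rdc_length_min,
                               cfg$rdc_length_max))
  len <- c(lenReg, lenRdc)
  isRdc <- c(rep(FALSE, nReg), rep(TRUE, cfg$n_rdc_genes))
  ord <- sample.int(cfg$n_genes)          # shuffle placement order
  len <- len[ord]; isRdc <- isRdc[ord]
  chromLen <- rep(floor(cfg$genome_size / cfg$n_chroms), cfg$n_chroms)
  chromLen[cfg$n_chroms] <- cfg$genome_size - sum(chromLen[-cfg$n_chroms])
  names(chromLen) <- paste0("chrS", seq_len(cfg$n_chroms))
  # greedy split of genes over chromosomes by remaining capacity
  chromOf <- integer(cfg$n_genes)
  used <- rep(0, cfg$n_chroms)
  for (i in seq_len(cfg$n_genes)) {
    need <- len[i] + cfg$min_gene_gap
    free <- chromLen - used - cfg$min_gene_gap
    j <- which.max(free - need)
    if (free[j] < need)
      stop("genes cannot be placed without overlap: genome too small")
    chromOf[i] <- j
    used[j] <- used[j] + need
  }
  starts <- integer(cfg$n_genes)
  chrom <- character(cfg$n_genes)
  for (j in seq_len(cfg$n_chroms)) {
    idx <- which(chromOf == j)
    if (length(idx) == 0L) next
    L <- chromLen[j]
    total <- sum(len[idx])
    nGap <- length(idx) + 1L
    extra <- L - total - nGap * cfg$min_gene_gap
    if (extra < 0) stop("genes cannot be placed without overlap")
    w <- stats::runif(nGap)
    gaps <- cfg$min_gene_gap + floor(extra * w / sum(w))
    pos <- cumsum(c(0, len[idx])) + cumsum(gaps)[seq_len(length(idx) + 1L)]
    starts[idx] <- pos[seq_along(idx)] + 1L
    chrom[idx] <- names(chromLen)[j]
  }
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  ids <- sprintf("gene%03d", seq_len(cfg$n_genes))
  list(chrom_sizes = chromLen,
       genes = data.frame(gene_id = ids, chrom = chrom, start = starts,
                          end = starts + len - 1L, length = len,
                          strand = strand, is_rdc = isRdc,
                          stringsAsFactors = FALSE))
}

.sim_assign_classes <- function(cfg, gt) {
  n <- nrow(gt)
  # skewed promoters: RDC-like genes stay unskewed
  nSkew <- round(cfg$fraction_skewed_promoters * n)
  cand <- which(!gt$is_rdc)
  if (nSkew > length(cand)) nSkew <- length(cand)
  gt$skewed <- FALSE
  gt$skewed[sample(cand, nSkew)] <- TRUE
  gt$skew_class_planted <- ifelse(gt$skewed, "strong", "none")
  # transcription classes: RDC genes forced active
  nActive <- round(cfg$frac_active * n)
  nAmb <- round(cfg$frac_ambiguous * n)
  cls <- rep("inactive", n)
  cls[gt$is_rdc] <- "active"
  pool <- sample(which(!gt$is_rdc))
  nActiveLeft <- max(0L, nActive - sum(gt$is_rdc))
  cls[pool[seq_len(nActiveLeft)]] <- "active"
  cls[pool[nActiveLeft + seq_len(min(nAmb, length(pool) - nActiveLeft))]] <-
    "ambiguous"
  gt$transcription_class <- cls
  # planted RPKM per class (boundaries respect the 0.025 / 0.0025 cutoffs)
  rpkm <- numeric(n)
  act <- cls == "active"
  rpkm[act] <- pmax(stats::rlnorm(sum(act), cfg$active_rpkm_meanlog,
                                  cfg$active_rpkm_sdlog), 0.03)
  amb <- cls == "ambiguous"
  rpkm[amb] <- 10^stats::runif(sum(amb), log10(0.0025), log10(0.024))
  ina <- cls == "inactive"
  rpkm[ina] <- stats::runif(sum(ina), 0, 0.0024)
  gt$rpkm <- rpkm
  # TSS-junction genes: the shortest active non-RDC genes, highly transcribed
  actCand <- which(act & !gt$is_rdc)
  ordLen <- actCand[order(gt$length[actCand], gt$gene_id[actCand])]
  tssGenes <- ordLen[seq_len(min(cfg$n_tss_junction_genes, length(ordLen)))]
  gt$is_tss_junction_gene <- seq_len(n) %in% tssGenes
  gt$rpkm[tssGenes] <- stats::rlnorm(length(tssGenes),
                                     cfg$tss_gene_rpkm_meanlog, 0.5)
  gt
}

.sim_tss <- function(gt) ifelse(gt$strand == "+", gt$start, gt$end)
.sim_tes <- function(gt) ifelse(gt$strand == "+", gt$end, gt$start)

.sim_skew_windows <- function(cfg, gt, chromLen) {
  idx <- which(gt$skewed)
  if (length(idx) == 0L) return(NULL)
  tssPos <- .sim_tss(gt)[idx]
  bodyLen <- floor(cfg$skew_body_fraction * gt$length[idx])
  plus <- gt$strand[idx] == "+"
  s <- ifelse(plus, pmin(tssPos - cfg$promoter_halfwidth, tssPos),
              pmin(tssPos - cfg$promoter_halfwidth, tssPos - bodyLen))
  e <- ifelse(plus, pmax(tssPos + cfg$promoter_halfwidth, tssPos + bodyLen),
              tssPos + cfg$promoter_halfwidth)
  s <- pmax(1L, as.integer(s))
  e <- pmin(as.integer(e), chromLen[gt$chrom[idx]])
  data.frame(chrom = gt$chrom[idx], start = s, end = e,
             strand = gt$strand[idx], stringsAsFactors = FALSE)
}

.sim_genome <- function(cfg, gt, chromLen) {
  bases <- c("A", "C", "G", "T")
  seqs <- lapply(chromLen, function(L)
    sample(bases, L, replace = TRUE))
  win <- .sim_skew_windows(cfg, gt, chromLen)
  pg <- cfg$skew_g_prob; pc <- cfg$skew_c_prob
  rest <- (1 - pg - pc) / 2
  for (i in seq_len(NROW(win))) {
    rng <- win$start[i]:win$end[i]
    if (win$strand[i] == "+") {
      # forward strand is the non-template (coding) strand: G-rich
      seqs[[win$chrom[i]]][rng] <- sample(bases, length(rng), replace = TRUE,
                                          prob = c(rest, pc, pg, rest))
    } else {
      # coding strand is the reverse complement: forward strand is C-rich
      seqs[[win$chrom[i]]][rng] <- sample(bases, length(rng), replace = TRUE,
                                          prob = c(rest, pg, pc, rest))
    }
  }
  DNAStringSet(vapply(seqs, paste, "", collapse = ""))
}

.sim_gene_models <- function(gt, chromLen) {
  g <- GRanges(gt$chrom, IRanges(gt$start, gt$end), strand = gt$strand,
               gene_id = gt$gene_id)
  seqlevels(g) <- names(chromLen)
  seqlengths(g) <- chromLen
  # two exons per gene separated by a central intron (where length allows)
  exons <- GRangesList(lapply(seq_len(nrow(gt)), function(i) {
    s <- gt$start[i]; e <- gt$end[i]; L <- gt$length[i]
    if (L >= 1200L) {
      q <- floor(L / 4)
      GRanges(gt$chrom[i], IRanges(c(s, e - q + 1L), c(s + q - 1L, e)))
    } else GRanges(gt$chrom[i], IRanges(s, e))
  }))
  names(exons) <- gt$gene_id
  GeneModels(g, exons)
}

.sim_gro <- function(cfg, gt, chromLen) {
  out <- lapply(names(chromLen), function(ch) Rle(0, chromLen[[ch]]))
  names(out) <- names(chromLen)
  perBp <- gt$rpkm * cfg$library_size / 1e9   # reads per bp within the gene
  for (i in seq_len(nrow(gt))) {
    if (perBp[i] == 0) next
    r <- out[[gt$chrom[i]]]
    r[gt$start[i]:gt$end[i]] <- perBp[i]
    out[[gt$chrom[i]]] <- r
  }
  methods::as(out, "RleList")
}

.sim_planted_peaks <- function(cfg, gt, chromLen) {
  mk <- function(chrom, center, w) {
    s <- pmax(1L, as.integer(round(center - w / 2)))
    GRanges(chrom, IRanges(s, pmin(s + as.integer(w) - 1L,
                                   chromLen[chrom])),
            seqlengths = chromLen)
  }
  peaks <- GRanges(seqlengths = chromLen)
  rdcHasPeak <- rep(FALSE, nrow(gt))
  for (i in seq_len(nrow(gt))) {
    cl <- gt$transcription_class[i]
    if (gt$is_rdc[i]) {
      if (stats::runif(1) < cfg$rdc_peak_prob) {
        # one body peak, kept clear of both gene ends
        center <- round(stats::runif(1, gt$start[i] + 2500,
                                     gt$end[i] - 2500))
        peaks <- c(peaks, mk(gt$chrom[i], center, cfg$peak_width_body))
        rdcHasPeak[i] <- TRUE
      }
      next
    }
    if (cl != "active") next
    tssPos <- .sim_tss(gt)[i]; tesPos <- .sim_tes(gt)[i]
    mid <- round((gt$start[i] + gt$end[i]) / 2)
    cand <- if (gt$skewed[i])
      c(mk(gt$chrom[i], tssPos, cfg$peak_width_tss),
        mk(gt$chrom[i], mid, cfg$peak_width_body),
        mk(gt$chrom[i], tesPos, cfg$peak_width_tes))
    else mk(gt$chrom[i], tesPos, cfg$peak_width_tes)
    peaks <- c(peaks, reduce(cand, min.gapwidth = cfg$peak_min_gap))
  }
  gt$rdc_has_peak <- rdcHasPeak
  peaks <- sort(reduce(peaks, min.gapwidth = cfg$peak_min_gap))
  seqlevels(peaks) <- names(chromLen)
  seqlengths(peaks) <- chromLen
  list(peaks = peaks, gt = gt)
}

.sim_drip <- function(cfg, peaks, chromLen) {
  out <- list()
  for (ch in names(chromLen)) {
    L <- chromLen[[ch]]
    nsteps <- ceiling(L / cfg$drip_step)
    lam <- rep(cfg$drip_background, nsteps)
    p <- peaks[as.character(seqnames(peaks)) == ch]
    for (i in seq_along(p)) {
      k1 <- ceiling((start(p)[i] + cfg$drip_step / 2) / cfg$drip_step)
      k2 <- floor((end(p)[i] + cfg$drip_step / 2) / cfg$drip_step)
      if (k2 >= k1) lam[k1:min(k2, nsteps)] <-
          cfg$drip_background * (1 + cfg$drip_snr)
    }
    counts <- stats::rpois(nsteps, lam)
    lens <- rep(cfg$drip_step, nsteps)
    lens[nsteps] <- L - cfg$drip_step * (nsteps - 1L)
    out[[ch]] <- Rle(as.numeric(counts), lens)
  }
  methods::as(out, "RleList")
}

.sim_junctions <- function(cfg, gt, chromLen) {
  mkJunc <- function(chrom, pos, id)
    GRanges(chrom, IRanges(as.integer(pos), width = 1L), gene_id = id,
            seqlengths = chromLen)
  tssJ <- GRanges(seqlengths = chromLen)
  rdcJ <- GRanges(seqlengths = chromLen)
  for (i in which(gt$is_tss_junction_gene)) {
    tssPos <- .sim_tss(gt)[i]
    lo <- max(1L, tssPos - cfg$promoter_halfwidth)
    hi <- min(chromLen[[gt$chrom[i]]], tssPos + cfg$promoter_halfwidth)
    pos <- round(stats::runif(cfg$n_junctions_per_tss_gene, lo, hi))
    tssJ <- c(tssJ, mkJunc(gt$chrom[i], pos, gt$gene_id[i]))
  }
  for (i in which(gt$is_rdc)) {
    tssPos <- .sim_tss(gt)[i]
    if (gt$strand[i] == "+") { lo <- tssPos + cfg$promoter_halfwidth + 1L
                               hi <- gt$end[i] }
    else { lo <- gt$start[i]; hi <- tssPos - cfg$promoter_halfwidth - 1L }
    pos <- round(stats::runif(cfg$n_junctions_per_rdc_gene, lo, hi))
    rdcJ <- c(rdcJ, mkJunc(gt$chrom[i], pos, gt$gene_id[i]))
  }
  seqlevels(tssJ) <- names(chromLen); seqlengths(tssJ) <- chromLen
  seqlevels(rdcJ) <- names(chromLen); seqlengths(rdcJ) <- chromLen
  list(tss = sort(tssJ), rdc = sort(rdcJ))
}

.sim_timing <- function(cfg, gt, chromLen) {
  out <- lapply(names(chromLen), function(ch) Rle(0, chromLen[[ch]]))
  names(out) <- names(chromLen)
  early <- which(gt$skewed & gt$transcription_class == "active")
  for (i in early) {
    L <- chromLen[[gt$chrom[i]]]
    s <- max(1L, gt$start[i] - cfg$timing_flank)
    e <- min(L, gt$end[i] + cfg$timing_flank)
    r <- out[[gt$chrom[i]]]; r[s:e] <- cfg$timing_early
    out[[gt$chrom[i]]] <- r
  }
  for (i in which(gt$is_rdc)) {
    r <- out[[gt$chrom[i]]]
    r[gt$start[i]:gt$end[i]] <- cfg$timing_late
    out[[gt$chrom[i]]] <- r
  }
  methods::as(out, "RleList")
}

.sim_gene_sets <- function(cfg, gt) {
  universe <- gt$gene_id
  skewedActive <- gt$gene_id[gt$skewed & gt$transcription_class == "active"]
  sets <- list()
  for (i in seq_len(cfg$n_planted_terms)) {
    nIn <- min(round(cfg$planted_term_purity * cfg$term_size),
               length(skewedActive))
    sets[[sprintf("planted_term_%02d", i)]] <-
      unique(c(sample(skewedActive, nIn),
               sample(setdiff(universe, skewedActive),
                      cfg$term_size - nIn)))
  }
  for (i in seq_len(cfg$n_terms)) {
    sets[[sprintf("background_term_%02d", i)]] <-
      sample(universe, cfg$term_size)
  }
  sets
}

#' Simulate a toy R-loop genome with planted ground truth
#'
#' Generates, deterministically from `config$seed`, everything the pipeline
#' consumes: a genome sequence with GC-skewed promoters, non-overlapping gene
#' models, GRO-seq coverage exactly recovering the planted RPKM, DRIP-seq
#' coverage with Poisson noise over planted R-loop peaks, TSS-class and
#' RDC-class breakpoint junctions, an early/late replication-timing track,
#' and a synthetic gene-set collection with planted enriched terms.
#'
#' @param config A [simConfig].
#' @return An object of class `RloopSimulation`: a list with `config`,
#'   `chrom_sizes`, `genome` (`DNAStringSet`), `genes` ([GeneModels-class]),
#'   `ground_truth` (per-gene data.frame), `peaks` (planted `GRanges`),
#'   `drip`, `gro`, `timing` (`RleList`s), `junctions_tss`, `junctions_rdc`
#'   (`GRanges`), and `gene_sets` (named list; planted terms are prefixed
#'   `planted_term_`).
#' @export
simulateRloopData <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  .with_seed(config$seed, {
    layout <- .sim_gene_layout(config)
    gt <- .sim_assign_classes(config, layout$genes)
    genome <- .sim_genome(config, gt, layout$chrom_sizes)
    gm <- .sim_gene_models(gt, layout$chrom_sizes)
    gro <- .sim_gro(config, gt, layout$chrom_sizes)
    pk <- .sim_planted_peaks(config, gt, layout$chrom_sizes)
    gt <- pk$gt
    drip <- .sim_drip(config, pk$peaks, layout$chrom_sizes)
    junc <- .sim_junctions(config, gt, layout$chrom_sizes)
    timing <- .sim_timing(config, gt, layout$chrom_sizes)
    sets <- .sim_gene_sets(config, gt)
    gt$timing_planted <- ifelse(gt$is_rdc, config$timing_late,
                                ifelse(gt$skewed &
                                         gt$transcription_class == "active",
                                       config$timing_early, 0))
    structure(list(config = config, chrom_sizes = layout$chrom_sizes,
                   genome = genome, genes = gm, ground_truth = gt,
                   peaks = pk$peaks, drip = drip, gro = gro, timing = timing,
                   junctions_tss = junc$tss, junctions_rdc = junc$rdc,
                   gene_sets = sets),
              class = "RloopSimulation")
  })
}

#' @export
print.RloopSimulation <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf(paste0("RloopSimulation: %s bp over %d chromosome(s), %d genes ",
                     "(%d skewed, %d RDC-like), %d planted peaks\n"),
              format(sum(x$chrom_sizes), big.mark = ","),
              length(x$chrom_sizes), nrow(gt), sum(gt$skewed), sum(gt$is_rdc),
              length(x$peaks)))
  invisible(x)
}

#' Write a simulation to standard genomics files
#'
#' Emits FASTA, chrom.sizes, GTF, three bedGraphs (DRIP, GRO, timing; the
#' timing track keeps explicit zero records so every position is reported),
#' three BEDs (planted peaks, TSS-class junctions, RDC-class junctions), a
#' GMT gene-set file, a per-gene ground-truth manifest (TSV) and the config
#' echo (YAML).
#'
#' @param sim An `RloopSimulation`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeXStringSet(sim$genome, p("genome.fa"))
  writeChromSizes(sim$chrom_sizes, p("genome.chrom.sizes"))
  writeGtfGenes(sim$genes, p("genes.gtf"))
  writeBedGraph(sim$drip, p("drip.bedGraph"))
  writeBedGraph(sim$gro, p("gro.bedGraph"))
  writeBedGraph(sim$timing, p("timing.bedGraph"), keepZero = TRUE)
  writeBed(sim$peaks, p("planted_peaks.bed"))
  jt <- sim$junctions_tss; mcols(jt)$name <- mcols(jt)$gene_id
  jr <- sim$junctions_rdc; mcols(jr)$name <- mcols(jr)$gene_id
  mcols(jt)$gene_id <- NULL; mcols(jr)$gene_id <- NULL
  writeBed(jt, p("junctions_tss.bed"))
  writeBed(jr, p("junctions_rdc.bed"))
  writeGmt(sim$gene_sets, p("gene_sets.gmt"))
  utils::write.table(sim$ground_truth, p("ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(c(unclass(sim$config),
                     list(library_size_declared = sim$config$library_size)),
                   p("sim_config.yaml"))
  out <- c(fasta = p("genome.fa"), chrom_sizes = p("genome.chrom.sizes"),
           gtf = p("genes.gtf"), drip = p("drip.bedGraph"),
           gro = p("gro.bedGraph"), timing = p("timing.bedGraph"),
           peaks = p("planted_peaks.bed"), junctions_tss = p("junctions_tss.bed"),
           junctions_rdc = p("junctions_rdc.bed"), gmt = p("gene_sets.gmt"),
           manifest = p("ground_truth.tsv"), config = p("sim_config.yaml"))
  invisible(out)
}
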