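.ANNOT_PRIORITY <- c("promoter", "5UTR", "3UTR", "exon", "TTS", "intron",
                     "intergenic")

#' Build a prioritized genomic-feature annotation
#'
#' Derives the category interval sets from gene models: promoter = TSS +/-
#' `promoterHalfwidth`, TTS = TES +/- `ttsHalfwidth`, intron = gene span minus
#' exons, intergenic = everything else; 5'/3' UTR sets may be supplied when
#' the gene source annotates them (genes without UTRs contribute exon/intron
#' only). Overlaps are resolved by the fixed priority promoter > 5UTR > 3UTR >
#' exon > TTS > intron > intergenic, after which the categories partition the
#' genome: every bp belongs to exactly one category. Windows running off a
#' chromosome end are clipped.
#'
#' @param gm A [GeneModels-class].
#' @param chromSizes Named chromosome lengths.
#' @param promoterHalfwidth,ttsHalfwidth Window half-widths in bp.
#' @param utr5,utr3 Optional `GRanges` of annotated UTRs.
#' @return An `AnnotationModel`: list with `categories` (named list of reduced
#'   `GRanges`), `chrom_sizes` and the window parameters.
#' @export
buildAnnotation <- function(gm, chromSizes, promoterHalfwidth = 2000L,
                            ttsHalfwidth = 1000L, utr5 = NULL, utr3 = NULL) {
  genome <- GRanges(names(chromSizes), IRanges(1L, as.integer(chromSizes)))
  seqlevels(genome) <- names(chromSizes)
  seqlengths(genome) <- chromSizes
  norm <- function(gr) {
    if (is.null(gr) || length(gr) == 0L) {
      gr <- GRanges()
    } else {
      strand(gr) <- "*"
      mcols(gr) <- NULL
      start(gr) <- pmax(1L, start(gr))
      end(gr) <- pmin(end(gr), chromSizes[as.character(seqnames(gr))])
    }
    seqlevels(gr) <- names(chromSizes)
    seqlengths(gr) <- chromSizes
    reduce(gr)
  }
  g <- geneRanges(gm)
  tesG <- tes(gm)
  exonAll <- unlist(geneExons(gm), use.names = FALSE)
  raw <- list(
    promoter = norm(promoterRegions(gm, promoterHalfwidth)),
    `5UTR` = norm(utr5),
    `3UTR` = norm(utr3),
    exon = norm(exonAll),
    TTS = norm(GRanges(seqnames(tesG),
                       IRanges(start(tesG) - ttsHalfwidth,
                               start(tesG) + ttsHalfwidth))),
    intron = GenomicRanges::setdiff(norm(g), norm(exonAll),
                                    ignore.strand = TRUE))
  acc <- GRanges()
  seqlevels(acc) <- names(chromSizes)
  seqlengths(acc) <- chromSizes
  categories <- list()
  for (nm in setdiff(.ANNOT_PRIORITY, "intergenic")) {
    categories[[nm]] <- GenomicRanges::setdiff(raw[[nm]], acc,
                                               ignore.strand = TRUE)
    acc <- reduce(c(acc, categories[[nm]]))
  }
  categories$intergenic <- GenomicRanges::setdiff(genome, acc,
                                                  ignore.strand = TRUE)
  structure(list(categories = categories, chrom_sizes = chromSizes,
                 promoter_halfwidth = as.integer(promoterHalfwidth),
                 tts_halfwidth = as.integer(ttsHalfwidth)),
            class = "AnnotationModel")
}

#' Single-label annotation of peaks
#'
#' Each peak is assigned the category of its midpoint (per-peak single-label
#' assignment, matching a per-peak pie-chart reading of the genomic
#' distribution).
#'
#' @param peaks A `GRanges`.
#' @param model An `AnnotationModel` from [buildAnnotation].
#' @return Factor of categories parallel to `peaks`.
#' @export
annotatePeaks <- function(peaks, model) {
  bad <- setdiff(unique(as.character(seqnames(peaks))),
                 names(model$chrom_sizes))
  if (length(bad))
    stop("peak chromosome(s) not in annotation model: ",
         paste(bad, collapse = ", "))
  mid <- GRanges(seqnames(peaks),
                 IRanges(floor((start(peaks) + end(peaks)) / 2), width = 1L))
  out <- rep(NA_character_, length(peaks))
  for (nm in names(model$categories)) {
    hit <- overlapsAny(mid, model$categories[[nm]], ignore.strand = TRUE)
    out[is.na(out) & hit] <- nm
  }
  factor(out, levels = .ANNOT_PRIORITY)
}

#' Observed vs expected annotation distribution
#'
#' Observed = fraction of peaks (by midpoint label) per category; expected =
#' fraction of genome bp per category. Both columns sum to 1.
#'
#' @param peaks Non-empty `GRanges`.
#' @param model An `AnnotationModel`.
#' @return data.frame: `category`, `observed`, `expected`, `peak_count`.
#' @export
observedVsExpected <- function(peaks, model) {
  if (length(peaks) == 0L) stop("need at least one peak")
  lab <- annotatePeaks(peaks, model)
  counts <- table(lab)
  bp <- vapply(model$categories, function(gr) sum(as.numeric(width(gr))), 0)
  data.frame(category = .ANNOT_PRIORITY,
             observed = as.numeric(counts[.ANNOT_PRIORITY] / length(peaks)),
             expected = as.numeric(bp[.ANNOT_PRIORITY] / sum(bp)),
             peak_count = as.integer(counts[.ANNOT_PRIORITY]),
             stringsAsFactors = FALSE)
}

#' Fraction of the genome covered by peaks
#'
#' Total merged peak bp divided by genome bp (duplicate or overlapping peaks
#' count once).
#'
#' @param peaks A `GRanges`.
#' @param chromSizes Named chromosome lengths.
#' @return A fraction between 0 and 1.
#' @export
genomeCoverageFraction <- function(peaks, chromSizes) {
  if (length(peaks) == 0L) return(0)
  sum(as.numeric(width(reduce(peaks, ignore.strand = TRUE)))) /
    sum(as.numeric(chromSizes))
}
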