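.BASE_LEVELS <- c("A", "C", "G", "T", "N")

#' Viterbi decoding of a nucleotide sequence under the GC-skew HMM
#'
#' Log-space Viterbi over the four skew states. `N` bases are emission-neutral
#' (probability 1 under every state). Ties resolve to the NONE state.
#'
#' @param model A [SkewHmm-class].
#' @param seq A single sequence: character string or [Biostrings::DNAString].
#' @return An [S4Vectors::Rle] of state labels, one per bp.
#' @export
viterbiSequence <- function(model, seq) {
  methods::validObject(model)
  s <- toupper(as.character(seq))
  if (nchar(s) == 0L) stop("empty sequence")
  idx <- match(strsplit(s, "")[[1]], .BASE_LEVELS)
  if (anyNA(idx)) stop("sequence contains characters outside A/C/G/T/N")
  logEmis <- rbind(t(log(model@emis)),      # rows A,C,G,T: log P(base | state)
                   N = rep(0, 4))           # N: likelihood-neutral
  le <- logEmis[idx, , drop = FALSE]
  path <- viterbi_decode_cpp(le, log(model@trans), log(rep(0.25, 4)))
  attributes(path) <- NULL
  Rle(factor(model@states[path], levels = model@states))
}

#' Run-length encode a state path into skew segments
#'
#' @param path State-label `Rle` (or vector) from [viterbiSequence].
#' @param chrom Chromosome name for the output ranges.
#' @return A `GRanges` partition of the decoded sequence with a `state`
#'   metadata column; NONE segments are retained (flagged by the label).
#' @export
segmentsFromPath <- function(path, chrom) {
  r <- Rle(as.character(path))
  ends <- cumsum(runLength(r))
  starts <- ends - runLength(r) + 1L
  GRanges(chrom, IRanges(starts, ends), state = runValue(r))
}

#' Decode a genome into GC-skew segments on both orientations
#'
#' Each chromosome is decoded twice: as-is (used for plus-strand genes, whose
#' non-template strand is the forward genomic strand) and as its reverse
#' complement (for minus-strand genes), with the latter's segments mapped back
#' to forward-strand coordinates. This orients decoding so a gene's coding
#' (non-template) strand is always read 5' to 3', which is what makes
#' G-rich-coding-strand promoters of minus-strand genes come out STRONG rather
#' than REVERSE.
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param model A [SkewHmm-class].
#' @return A list with `forward` and `reverse` elements, each a `GRanges` of
#'   segments (forward-genomic coordinates) with a `state` column.
#' @export
skewSegmentsGenome <- function(genome, model = skewHmm("stringent")) {
  fwd <- list(); rev <- list()
  for (ch in names(genome)) {
    L <- length(genome[[ch]])
    f <- segmentsFromPath(viterbiSequence(model, genome[[ch]]), ch)
    seqlevels(f) <- names(genome)
    fwd[[ch]] <- f
    segR <- segmentsFromPath(
      viterbiSequence(model, reverseComplement(genome[[ch]])), ch)
    # map revcomp coordinates back to the forward strand
    s <- L + 1L - end(segR); e <- L + 1L - start(segR)
    segR <- GRanges(ch, IRanges(s, e), state = mcols(segR)$state)
    seqlevels(segR) <- names(genome)
    rev[[ch]] <- sort(segR)
  }
  list(forward = sort(do.call(c, unname(fwd))),
       reverse = sort(do.call(c, unname(rev))))
}

.SKEW_CLASS_PRIORITY <- c("strong", "weak", "reverse", "none")

#' Classify genes into GC-skew classes
#'
#' Assigns each gene one of the four skew classes (`strong`, `weak`, `none`,
#' `reverse`) from the decoded segments overlapping its promoter (TSS +/-
#' `promoterHalfwidth`). When several skew states overlap the promoter the
#' highest-priority one wins (strong > weak > reverse > none). Minus-strand
#' genes are classified against the reverse-complement decode, so classes are
#' always relative to the gene's own non-template strand.
#'
#' @param gm A [GeneModels-class].
#' @param segments Output of [skewSegmentsGenome].
#' @param promoterHalfwidth Promoter half-width in bp.
#' @param scope `"promoter"` (default, promoter-anchored classes) or
#'   `"gene"` (consider segments anywhere in the gene span plus promoter).
#' @return Named character vector, one class per gene (a partition of the gene
#'   universe).
#' @export
classifyGeneSkew <- function(gm, segments, promoterHalfwidth = 2000L,
                             scope = c("promoter", "gene")) {
  scope <- match.arg(scope)
  win <- promoterRegions(gm, promoterHalfwidth)
  if (scope == "gene") {
    g <- geneRanges(gm)
    win <- GRanges(seqnames(win),
                   IRanges(pmin(start(win), start(g)), pmax(end(win), end(g))),
                   gene_id = mcols(win)$gene_id)
  }
  plus <- as.character(strand(geneRanges(gm))) == "+"
  segChroms <- unique(c(as.character(seqnames(segments$forward)),
                        as.character(seqnames(segments$reverse))))
  bad <- setdiff(unique(as.character(seqnames(win))), segChroms)
  if (length(bad))
    stop("gene chromosome(s) absent from skew decode: ",
         paste(bad, collapse = ", "))
  pick <- function(windows, segs) {
    hits <- findOverlaps(windows, segs, minoverlap = 1L, ignore.strand = TRUE)
    st <- tolower(mcols(segs)$state[S4Vectors::subjectHits(hits)])
    pr <- match(st, .SKEW_CLASS_PRIORITY)
    best <- tapply(pr, S4Vectors::queryHits(hits), min)
    out <- rep("none", length(windows))
    out[as.integer(names(best))] <- .SKEW_CLASS_PRIORITY[best]
    out
  }
  cls <- character(length(gm))
  if (any(plus)) cls[plus] <- pick(win[plus], segments$forward)
  if (any(!plus)) cls[!plus] <- pick(win[!plus], segments$reverse)
  stats::setNames(cls, geneIds(gm))
}

#' Windowed GC-skew profile
#'
#' Diagnostic (G-C)/(G+C) over consecutive non-overlapping windows.
#'
#' @param seq A character string or `DNAString`.
#' @param window Window size in bp (> 0).
#' @return A data.frame with `start`, `end` (1-based closed), `skew`, and
#'   `undefined` (TRUE where the window has no G or C; skew reported as 0
#'   there).
#' @export
skewProfile <- function(seq, window = 100L) {
  if (window <= 0) stop("window must be > 0")
  s <- Biostrings::DNAString(toupper(as.character(seq)))
  L <- length(s)
  starts <- seq.int(1L, L, by = window)
  ends <- pmin(starts + window - 1L, L)
  v <- Views(s, start = starts, end = ends)
  freq <- Biostrings::letterFrequency(v, c("G", "C"))
  g <- freq[, "G"]; c0 <- freq[, "C"]
  undef <- (g + c0) == 0
  skew <- ifelse(undef, 0, (g - c0) / (g + c0))
  data.frame(start = starts, end = ends, skew = skew, undefined = undef)
}
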