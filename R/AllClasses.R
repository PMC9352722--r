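#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<-
#' @importFrom Biostrings DNAStringSet reverseComplement letterFrequency
#'   readDNAStringSet writeXStringSet
#' @useDynLib rloopscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Gene models with exon structure
#'
#' A container for gene models: one genomic span per gene (with mandatory
#' `+`/`-` strand) plus an exon [GenomicRanges::GRangesList] parallel to the
#' genes. The transcription start site (TSS) is the 5' end of the span on the
#' gene's strand and the transcription end site (TES) the 3' end.
#'
#' @slot genes A [GenomicRanges::GRanges] with a `gene_id` metadata column.
#' @slot exons A [GenomicRanges::GRangesList] named by `gene_id`; exons of each
#'   gene are sorted, non-overlapping and contained in the gene span.
#' @export
setClass("GeneModels", representation(genes = "GRanges", exons = "GRangesList"))

setValidity("GeneModels", function(object) {
  g <- object@genes
  msg <- character()
  if (is.null(mcols(g)$gene_id)) msg <- c(msg, "genes need a 'gene_id' column")
  else {
    if (anyDuplicated(mcols(g)$gene_id)) msg <- c(msg, "duplicate gene_id")
    if (!identical(names(object@exons), as.character(mcols(g)$gene_id)))
      msg <- c(msg, "exons must be named by gene_id, parallel to genes")
  }
  if (any(!as.character(strand(g)) %in% c("+", "-")))
    msg <- c(msg, "gene strand must be '+' or '-'")
  if (any(width(g) <= 0)) msg <- c(msg, "gene length must be > 0")
  for (i in seq_along(object@exons)) {
    ex <- object@exons[[i]]
    if (length(ex) == 0L) next
    if (is.unsorted(start(ex)) ||
        (length(ex) > 1L && any(start(ex)[-1] <= end(ex)[-length(ex)]))) {
      msg <- c(msg, "exons must be sorted and non-overlapping"); break
    }
    if (min(start(ex)) < start(g)[i] || max(end(ex)) > end(g)[i]) {
      msg <- c(msg, sprintf("exons of '%s' extend outside the gene span",
                            mcols(g)$gene_id[i])); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModels object
#'
#' @param genes `GRanges` with strand `+`/`-` and a `gene_id` metadata column.
#' @param exons Optional `GRangesList` named by gene id; defaults to one exon
#'   spanning each gene (single-exon models).
#' @return A [GeneModels-class] object.
#' @export
GeneModels <- function(genes, exons = NULL) {
  ids <- as.character(mcols(genes)$gene_id)
  if (is.null(exons)) {
    exons <- GRangesList(lapply(seq_along(genes), function(i) {
      g <- genes[i]; mcols(g) <- NULL; g
    }))
    names(exons) <- ids
  }
  new("GeneModels", genes = genes, exons = exons[ids])
}

#' @describeIn GeneModels-class number of genes
#' @param x,object A `GeneModels` object.
#' @export
setMethod("length", "GeneModels", function(x) length(x@genes))

setMethod("show", "GeneModels", function(object) {
  cat(sprintf("GeneModels with %d genes on %d chromosome(s)\n",
              length(object), length(unique(as.character(seqnames(object@genes))))))
})

#' @describeIn GeneModels-class subset genes
#' @param i index
#' @param j,drop,... unused
#' @export
setMethod("[", "GeneModels", function(x, i, j, ..., drop = TRUE) {
  new("GeneModels", genes = x@genes[i],
      exons = x@exons[as.character(mcols(x@genes)$gene_id[i])])
})

#' Accessors for GeneModels
#'
#' `geneRanges()` returns the gene spans, `geneIds()` the gene identifiers,
#' `geneExons()` the exon list, `tss()`/`tes()` width-1 `GRanges` at the
#' transcription start/end site, and `promoterRegions()` the TSS +/- `halfwidth`
#' windows (clipped to chromosome bounds when lengths are known).
#'
#' @param x A [GeneModels-class] object.
#' @return A `GRanges` (or `GRangesList`/`character` as appropriate).
#' @export
geneRanges <- function(x) x@genes

#' @rdname geneRanges
#' @export
geneIds <- function(x) as.character(mcols(x@genes)$gene_id)

#' @rdname geneRanges
#' @export
geneExons <- function(x) x@exons

#' @rdname geneRanges
#' @export
tss <- function(x) {
  g <- x@genes
  pos <- ifelse(as.character(strand(g)) == "+", start(g), end(g))
  gr <- GRanges(seqnames(g), IRanges(pos, width = 1L), strand = strand(g),
                gene_id = mcols(g)$gene_id)
  seqlengths(gr) <- seqlengths(g)
  gr
}

#' @rdname geneRanges
#' @export
tes <- function(x) {
  g <- x@genes
  pos <- ifelse(as.character(strand(g)) == "+", end(g), start(g))
  gr <- GRanges(seqnames(g), IRanges(pos, width = 1L), strand = strand(g),
                gene_id = mcols(g)$gene_id)
  seqlengths(gr) <- seqlengths(g)
  gr
}

#' @rdname geneRanges
#' @param halfwidth Window half-width in bp (promoter is TSS +/- `halfwidth`).
#' @export
promoterRegions <- function(x, halfwidth = 2000L) {
  t <- tss(x)
  p <- GRanges(seqnames(t),
               IRanges(pmax(1L, start(t) - halfwidth), start(t) + halfwidth),
               strand = strand(t), gene_id = mcols(t)$gene_id)
  sl <- seqlengths(t)
  if (!any(is.na(sl))) {
    lim <- sl[as.character(seqnames(p))]
    end(p) <- pmin(end(p), lim)
  }
  seqlengths(p) <- sl
  p
}

#' Two-state Gaussian HMM for peak calling
#'
#' Model for segmenting log1p-transformed binned DRIP-seq coverage into
#' background (state 1) and enriched (state 2) bins. Emissions are Gaussian per
#' state; `mu[2] >= mu[1]` is maintained by relabeling after fitting.
#'
#' @slot init Initial state probabilities (length 2).
#' @slot trans 2x2 transition matrix, rows sum to 1.
#' @slot mu,sigma Per-state Gaussian emission mean and sd (> 0) on the log1p
#'   scale.
#' @slot loglik Baum-Welch log-likelihood trace (empty before fitting).
#' @export
setClass("PeakHmm", representation(init = "numeric", trans = "matrix",
                                   mu = "numeric", sigma = "numeric",
                                   loglik = "numeric"))

setValidity("PeakHmm", function(object) {
  msg <- character()
  if (length(object@init) != 2L || abs(sum(object@init) - 1) > 1e-6 ||
      any(object@init < 0))
    msg <- c(msg, "init must be 2 probabilities summing to 1")
  if (!all(dim(object@trans) == c(2L, 2L)) ||
      any(abs(rowSums(object@trans) - 1) > 1e-6) || any(object@trans < 0))
    msg <- c(msg, "trans must be a 2x2 stochastic matrix")
  if (length(object@mu) != 2L) msg <- c(msg, "mu must have length 2")
  if (length(object@sigma) != 2L || any(object@sigma <= 0))
    msg <- c(msg, "sigma must be 2 positive values")
  if (length(msg)) msg else TRUE
})

#' Construct a PeakHmm
#' @param init,trans,mu,sigma See [PeakHmm-class].
#' @return A `PeakHmm` object.
#' @export
PeakHmm <- function(init = c(0.9, 0.1),
                    trans = matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
                    mu = c(0, 1), sigma = c(0.5, 0.5)) {
  new("PeakHmm", init = init, trans = trans, mu = mu, sigma = sigma,
      loglik = numeric(0))
}

setMethod("show", "PeakHmm", function(object) {
  cat("PeakHmm (2-state Gaussian on log1p coverage)\n")
  cat(sprintf("  background: mu=%.4f sd=%.4f\n", object@mu[1], object@sigma[1]))
  cat(sprintf("  enriched:   mu=%.4f sd=%.4f\n", object@mu[2], object@sigma[2]))
  cat(sprintf("  self-transitions: %.4f / %.4f", object@trans[1, 1],
              object@trans[2, 2]))
  if (length(object@loglik))
    cat(sprintf("; fitted, %d EM iterations, logLik %.3f",
                length(object@loglik), object@loglik[length(object@loglik)]))
  cat("\n")
})

.SKEW_STATES <- c("NONE", "STRONG", "WEAK", "REVERSE")

#' Four-state GC-skew HMM
#'
#' Nucleotide-emission HMM over states NONE, STRONG, WEAK and REVERSE used to
#' segment genomic sequence into GC-skew classes. STRONG has the largest
#' P(G)-P(C) margin, REVERSE is its complement mirror, NONE is uniform. The
#' NONE state is listed first so that Viterbi ties resolve to no-skew.
#'
#' @slot states State labels (fixed order: NONE, STRONG, WEAK, REVERSE).
#' @slot emis 4x4 emission matrix, rows = states, columns = A,C,G,T.
#' @slot trans 4x4 transition matrix.
#' @slot stringency Free-text label ("stringent" or "lenient" for the built-in
#'   parameter sets).
#' @export
setClass("SkewHmm", representation(states = "character", emis = "matrix",
                                   trans = "matrix", stringency = "character"))

setValidity("SkewHmm", function(object) {
  msg <- character()
  if (!identical(object@states, .SKEW_STATES))
    msg <- c(msg, "states must be NONE, STRONG, WEAK, REVERSE in that order")
  if (!all(dim(object@emis) == c(4L, 4L)) ||
      any(abs(rowSums(object@emis) - 1) > 1e-6) || any(object@emis < 0))
    msg <- c(msg, "emis must be 4x4 with rows summing to 1")
  if (!all(dim(object@trans) == c(4L, 4L)) ||
      any(abs(rowSums(object@trans) - 1) > 1e-6) || any(object@trans < 0))
    msg <- c(msg, "trans must be a 4x4 stochastic matrix")
  if (length(msg) == 0L) {
    gc <- object@emis[, 3] - object@emis[, 2]   # P(G) - P(C) per state
    if (gc[2] < max(gc)) msg <- c(msg, "STRONG must have max P(G)-P(C)")
    if (object@emis[4, 2] < object@emis[4, 3])
      msg <- c(msg, "REVERSE must have P(C) >= P(G)")
  }
  if (length(msg)) msg else TRUE
})

#' Built-in GC-skew HMM parameter sets
#'
#' Returns the four-state skew model at the requested stringency. Stringency
#' controls the self-transition probability, i.e. the expected length of a
#' state segment: `"stringent"` uses 1 - 1e-6 (expected segment ~1 Mb) and is
#' the default for gene classification; `"lenient"` uses 1 - 1/7600 (~7.6 kb)
#' and suits finer-grained metaplot segmentation. Emission defaults:
#' STRONG P(G)=0.40, P(C)=0.20; WEAK P(G)=0.30, P(C)=0.20; NONE uniform;
#' REVERSE the complement mirror of STRONG. All parameters are overridable.
#'
#' @param stringency `"stringent"` or `"lenient"`.
#' @param emis Optional 4x4 emission matrix (rows NONE, STRONG, WEAK, REVERSE;
#'   columns A, C, G, T) overriding the defaults.
#' @param selfTransition Optional self-transition probability overriding the
#'   stringency preset; remaining mass is split evenly across other states.
#' @return A [SkewHmm-class] object.
#' @export
skewHmm <- function(stringency = c("stringent", "lenient"), emis = NULL,
                    selfTransition = NULL) {
  stringency <- match.arg(stringency)
  if (is.null(selfTransition))
    selfTransition <- if (stringency == "stringent") 1 - 1e-6 else 1 - 1 / 7600
  if (is.null(emis)) {
    emis <- rbind(NONE    = c(0.25, 0.25, 0.25, 0.25),
                  STRONG  = c(0.20, 0.20, 0.40, 0.20),
                  WEAK    = c(0.25, 0.20, 0.30, 0.25),
                  REVERSE = c(0.20, 0.40, 0.20, 0.20))
    colnames(emis) <- c("A", "C", "G", "T")
  }
  off <- (1 - selfTransition) / 3
  trans <- matrix(off, 4, 4)
  diag(trans) <- selfTransition
  dimnames(trans) <- list(.SKEW_STATES, .SKEW_STATES)
  new("SkewHmm", states = .SKEW_STATES, emis = emis, trans = trans,
      stringency = stringency)
}

setMethod("show", "SkewHmm", function(object) {
  cat(sprintf("SkewHmm (4-state GC-skew model, %s)\n", object@stringency))
  cat(sprintf("  self-transition: %g\n", object@trans[1, 1]))
  cat("  P(G)-P(C) per state:",
      paste(sprintf("%s=%.2f", object@states, object@emis[, 3] - object@emis[, 2]),
            collapse = " "), "\n")
})
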