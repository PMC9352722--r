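#' Analysis configuration
#'
#' Collects the thresholds used across the pipeline in one place: the GRO-seq
#' RPKM transcription-class cutoffs (active >= 0.025, ambiguous >= 0.0025 and
#' < 0.025, inactive below; both lower bounds inclusive), the 2 kb promoter
#' half-width, the 2 kb junction-proximity window, the +/-5 percent
#' similar-transcription tolerance, and the peak-caller binning parameters.
#'
#' @param active_threshold,ambiguous_threshold RPKM class boundaries.
#' @param promoter_halfwidth,tts_halfwidth,junction_window Windows in bp.
#' @param similar_transcription_tolerance Fractional tolerance for
#'   [similarTranscription].
#' @param match_log10_cap Hard cap on |delta log10 RPKM| in
#'   [matchByTranscription].
#' @param bin_size,min_bins,merge_gap_bins Peak-caller parameters.
#' @param seed Seed for the stochastic steps (down-sampling, matching ties).
#' @return A classed list.
#' @export
analysisConfig <- function(active_threshold = 0.025,
                           ambiguous_threshold = 0.0025,
                           promoter_halfwidth = 2000L,
                           tts_halfwidth = 1000L,
                           junction_window = 2000L,
                           similar_transcription_tolerance = 0.05,
                           match_log10_cap = 0.5,
                           bin_size = 500L, min_bins = 3L, merge_gap_bins = 1L,
                           seed = 1L) {
  stopifnot(ambiguous_threshold > 0, active_threshold > ambiguous_threshold,
            promoter_halfwidth > 0, junction_window > 0, bin_size > 0)
  structure(list(active_threshold = active_threshold,
                 ambiguous_threshold = ambiguous_threshold,
                 promoter_halfwidth = as.integer(promoter_halfwidth),
                 tts_halfwidth = as.integer(tts_halfwidth),
                 junction_window = as.integer(junction_window),
                 similar_transcription_tolerance = similar_transcription_tolerance,
                 match_log10_cap = match_log10_cap,
                 bin_size = as.integer(bin_size),
                 min_bins = as.integer(min_bins),
                 merge_gap_bins = as.integer(merge_gap_bins),
                 seed = as.integer(seed)),
            class = "AnalysisConfig")
}

#' RPKM from read counts
#'
#' RPKM = counts x 1e9 / (length_bp x library_size): reads per kilobase of
#' feature per million mapped reads.
#'
#' @param counts Read count(s) over the feature.
#' @param lengthBp Feature length(s) in bp (> 0).
#' @param librarySize Total mapped reads (> 0).
#' @return Numeric RPKM, vectorized over `counts`/`lengthBp`.
#' @export
computeRpkm <- function(counts, lengthBp, librarySize) {
  if (any(librarySize <= 0)) stop("library size must be > 0")
  if (any(lengthBp <= 0)) stop("feature length must be > 0")
  counts * 1e9 / (lengthBp * librarySize)
}

#' Per-gene GRO-seq expression table
#'
#' Counts nascent-transcription signal over each full gene span (GRO-seq
#' measures unspliced transcription, so exon structure is ignored), converts
#' to RPKM and assigns the three transcription classes.
#'
#' @param gm A [GeneModels-class].
#' @param track GRO-seq coverage `RleList` in units of reads per bp (so that
#'   the sum over a span is a read count).
#' @param librarySize Total mapped reads; defaults to the genome-wide sum of
#'   the track.
#' @param config An [analysisConfig].
#' @return data.frame: `gene_id`, `length`, `counts`, `rpkm`, `class`.
#' @export
expressionTable <- function(gm, track, librarySize = NULL,
                            config = analysisConfig()) {
  g <- geneRanges(gm)
  bad <- setdiff(unique(as.character(seqnames(g))), names(track))
  if (length(bad))
    stop("track missing chromosome(s): ", paste(bad, collapse = ", "))
  if (is.null(librarySize))
    librarySize <- sum(vapply(track, function(r) sum(as.numeric(r)), 0))
  counts <- vapply(seq_along(g), function(i) {
    r <- track[[as.character(seqnames(g)[i])]]
    sum(as.numeric(Views(r, start = start(g)[i], end = end(g)[i])[[1]]))
  }, 0)
  rpkm <- computeRpkm(counts, width(g), librarySize)
  data.frame(gene_id = geneIds(gm), length = width(g), counts = counts,
             rpkm = rpkm,
             class = classifyTranscription(rpkm, config),
             stringsAsFactors = FALSE)
}

#' Transcription class from RPKM
#'
#' `active` for RPKM >= `active_threshold`, `ambiguous` for RPKM in
#' [`ambiguous_threshold`, `active_threshold`), `inactive` below. Both lower
#' boundaries are inclusive.
#'
#' @param rpkm Numeric RPKM values (>= 0).
#' @param config An [analysisConfig].
#' @return Character vector in {"active", "ambiguous", "inactive"}.
#' @export
classifyTranscription <- function(rpkm, config = analysisConfig()) {
  if (any(rpkm < 0)) stop("negative RPKM")
  ifelse(rpkm >= config$active_threshold, "active",
         ifelse(rpkm >= config$ambiguous_threshold, "ambiguous", "inactive"))
}

#' Similar transcription test
#'
#' Two RPKM values count as similarly transcribed when they differ by at most
#' `tolerance` (default 5 percent) of the larger value; (0, 0) is similar.
#'
#' @param rpkmA,rpkmB Non-negative RPKM values (vectorized).
#' @param tolerance Fractional tolerance.
#' @return Logical.
#' @export
similarTranscription <- function(rpkmA, rpkmB, tolerance = 0.05) {
  stopifnot(all(rpkmA >= 0), all(rpkmB >= 0))
  mx <- pmax(rpkmA, rpkmB)
  ifelse(mx == 0, TRUE, abs(rpkmA - rpkmB) <= tolerance * mx)
}

#' Build a transcription-rate-matched control gene set
#'
#' Greedy nearest-neighbour matching in log10(RPKM + 1e-6) without
#' replacement: targets are processed in a fixed internal order (descending
#' RPKM, gene id as tie-break), candidates within the +/-5 percent
#' similar-transcription band are preferred, otherwise the nearest available
#' candidate is taken; a target with no candidate within `cap` log10 units is
#' dropped and reported. The result is deterministic and independent of input
#' order.
#'
#' @param targetIds,poolIds Disjoint character vectors of gene ids.
#' @param rpkm Named numeric RPKM covering both sets.
#' @param tolerance Preferred-band fractional tolerance.
#' @param cap Hard cap on |delta log10(RPKM + 1e-6)|.
#' @param seed Accepted for interface stability; matching is fully
#'   deterministic, so the seed only matters if future tie-break policies
#'   randomize.
#' @return List: `matched` (named character, target -> matched pool gene) and
#'   `dropped` (targets without an acceptable match).
#' @export
matchByTranscription <- function(targetIds, poolIds, rpkm, tolerance = 0.05,
                                 cap = 0.5, seed = 1L) {
  if (length(poolIds) == 0L) stop("empty candidate pool")
  if (length(intersect(targetIds, poolIds)))
    stop("target set and pool must be disjoint")
  if (!all(c(targetIds, poolIds) %in% names(rpkm)))
    stop("rpkm must cover all target and pool genes")
  lg <- function(ids) log10(rpkm[ids] + 1e-6)
  ord <- order(-rpkm[targetIds], targetIds)
  targets <- targetIds[ord]
  avail <- poolIds[order(poolIds)]
  matched <- character(0); dropped <- character(0)
  for (t in targets) {
    if (length(avail) == 0L) { dropped <- c(dropped, t); next }
    d <- abs(lg(avail) - lg(t))
    pref <- similarTranscription(rep(rpkm[[t]], length(avail)), rpkm[avail],
                                 tolerance)
    cand <- if (any(pref)) which(pref) else which(d <= cap)
    if (length(cand) == 0L) { dropped <- c(dropped, t); next }
    best <- cand[order(d[cand], avail[cand])][1]
    matched[t] <- avail[best]
    avail <- avail[-best]
  }
  list(matched = matched, dropped = dropped)
}
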