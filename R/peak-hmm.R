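#' Bin a coverage track
#'
#' Partitions each chromosome into consecutive `binSize`-bp bins (the trailing
#' partial bin is kept) and records the mean coverage per bin, uncovered
#' positions counting as zero.
#'
#' @param track An `RleList` coverage track (e.g. from [readBedGraph]).
#' @param binSize Bin width in bp (> 0).
#' @param chromSizes Named chromosome lengths; every chromosome listed must be
#'   present in `track`.
#' @return A `BinnedTrack`: a list with `bins` (named list of numeric vectors,
#'   one value per bin), `bin_size` and `chrom_sizes`.
#' @export
binCoverage <- function(track, binSize, chromSizes) {
  if (binSize <= 0) stop("binSize must be > 0")
  binSize <- as.integer(binSize)
  bad <- setdiff(names(chromSizes), names(track))
  if (length(bad))
    stop("track missing chromosome(s): ", paste(bad, collapse = ", "))
  bins <- lapply(names(chromSizes), function(ch) {
    L <- chromSizes[[ch]]
    r <- track[[ch]]
    if (length(r) < L) r <- c(r, Rle(0, L - length(r)))
    n <- ceiling(L / binSize)
    starts <- seq.int(1L, by = binSize, length.out = n)
    ends <- pmin(starts + binSize - 1L, L)
    as.numeric(viewMeans(Views(r, start = starts, end = ends)))
  })
  names(bins) <- names(chromSizes)
  structure(list(bins = bins, bin_size = binSize, chrom_sizes = chromSizes),
            class = "BinnedTrack")
}

#' Sum coverage tracks position-wise
#'
#' Pools replicate coverage tracks (e.g. multiple DRIP samples) into one track
#' by per-bp addition.
#'
#' @param tracks A list of `RleList` tracks over the same chromosome universe.
#' @return An `RleList`.
#' @export
poolTracks <- function(tracks) {
  if (length(tracks) == 0L) stop("no tracks to pool")
  universe <- names(tracks[[1]])
  for (t in tracks)
    if (!setequal(names(t), universe))
      stop("tracks cover different chromosome universes")
  out <- tracks[[1]][universe]
  for (t in tracks[-1]) {
    for (ch in universe) {
      a <- out[[ch]]; b <- t[[ch]]
      if (length(a) != length(b))
        stop("chromosome length mismatch on ", ch)
      out[[ch]] <- a + b
    }
  }
  out
}

.log1p_bins <- function(binned) lapply(binned$bins, log1p)

#' Fit the two-state peak HMM by Baum-Welch
#'
#' Expectation-maximisation on log1p-transformed binned coverage, treating
#' chromosomes as independent observation sequences. The log-likelihood is
#' non-decreasing across iterations; fitting stops when its change drops below
#' `tol` or after `maxIter` iterations. States are relabeled afterwards so
#' state 2 ("enriched") has the larger emission mean.
#'
#' When `init` is `NULL`, starting values come from a quantile split:
#' background from bins at or below the median, enriched from the top decile.
#'
#' @param binned A `BinnedTrack` from [binCoverage].
#' @param init Optional starting [PeakHmm-class].
#' @param maxIter,tol EM stopping rule.
#' @return A fitted [PeakHmm-class] with the log-likelihood trace in
#'   `@loglik`.
#' @export
fitPeakHmm <- function(binned, init = NULL, maxIter = 200L, tol = 1e-4) {
  xs <- .log1p_bins(binned)
  all <- unlist(xs, use.names = FALSE)
  if (length(unique(all)) < 2L)
    stop("degenerate input: all bins equal; use a fixed-parameter model and ",
         "viterbiPeaks() directly")
  if (is.null(init)) {
    med <- stats::median(all)
    q90 <- stats::quantile(all, 0.9, names = FALSE)
    lo <- all[all <= med]; hi <- all[all >= q90]
    sd0 <- max(stats::sd(all), 1e-3)
    init <- PeakHmm(init = c(0.9, 0.1),
                    trans = matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
                    mu = c(mean(lo), mean(hi)),
                    sigma = c(max(stats::sd(lo), 1e-3, na.rm = TRUE),
                              max(stats::sd(hi), sd0 / 2, na.rm = TRUE)))
  }
  pi0 <- init@init; A <- init@trans; mu <- init@mu; sigma <- init@sigma
  llTrace <- numeric(0)
  for (iter in seq_len(maxIter)) {
    ll <- 0
    g1 <- c(0, 0)                       # initial-state posteriors
    xi <- matrix(0, 2, 2)
    gSum <- c(0, 0); gxSum <- c(0, 0); gx2Sum <- c(0, 0)
    for (x in xs) {
      emis <- cbind(stats::dnorm(x, mu[1], sigma[1]),
                    stats::dnorm(x, mu[2], sigma[2]))
      emis[emis < 1e-300] <- 1e-300
      fb <- forward_backward_cpp(emis, A, pi0)
      ll <- ll + fb$loglik
      g <- fb$gamma
      g1 <- g1 + g[1, ]
      xi <- xi + fb$xi_sum
      gSum <- gSum + colSums(g)
      gxSum <- gxSum + colSums(g * x)
      gx2Sum <- gx2Sum + colSums(g * x^2)
    }
    llTrace <- c(llTrace, ll)
    # M-step
    pi0 <- g1 / sum(g1)
    A <- xi / rowSums(xi)
    muNew <- gxSum / gSum
    sigmaNew <- sqrt(pmax(gx2Sum / gSum - muNew^2, 1e-6))
    mu <- muNew; sigma <- pmax(sigmaNew, 1e-3)
    if (iter > 1 && abs(llTrace[iter] - llTrace[iter - 1]) < tol) break
  }
  if (mu[1] > mu[2]) {                  # relabel: state 2 = enriched
    mu <- rev(mu); sigma <- rev(sigma); pi0 <- rev(pi0)
    A <- A[2:1, 2:1]
  }
  out <- PeakHmm(init = pi0, trans = A, mu = mu, sigma = sigma)
  out@loglik <- llTrace
  out
}

#' Viterbi decoding of binned coverage
#'
#' Most-probable state path under a [PeakHmm-class], per chromosome. Ties are
#' broken toward the background state (conservative peak calls).
#'
#' @param model A `PeakHmm`.
#' @param binned A `BinnedTrack`.
#' @return Named list of integer vectors (1 = background, 2 = enriched).
#' @export
viterbiPeaks <- function(model, binned) {
  methods::validObject(model)
  lt <- log(model@trans)
  li <- log(model@init)
  out <- lapply(.log1p_bins(binned), function(x) {
    le <- cbind(stats::dnorm(x, model@mu[1], model@sigma[1], log = TRUE),
                stats::dnorm(x, model@mu[2], model@sigma[2], log = TRUE))
    p <- viterbi_decode_cpp(le, lt, li)
    attributes(p) <- NULL
    p
  })
  names(out) <- names(binned$bins)
  out
}

#' Convert a state path to peak intervals
#'
#' Maximal runs of the enriched state become bp intervals; runs separated by
#' at most `mergeGapBins` background bins are merged first, then merged runs
#' spanning fewer than `minBins` bins are dropped.
#'
#' @param paths Named list of integer state paths (from [viterbiPeaks]).
#' @param binSize Bin width in bp used to produce the paths.
#' @param chromSizes Named chromosome lengths (peaks are clipped to them).
#' @param minBins Minimum run length, in bins, for a peak to be reported.
#' @param mergeGapBins Maximum number of intervening background bins bridged
#'   when merging adjacent runs.
#' @return A sorted, non-overlapping `GRanges` of peaks.
#' @export
callPeaks <- function(paths, binSize, chromSizes, minBins = 3L,
                      mergeGapBins = 1L) {
  res <- list()
  for (ch in names(paths)) {
    p <- paths[[ch]]
    r <- S4Vectors::Rle(p == 2L)
    ends <- cumsum(runLength(r))
    starts <- ends - runLength(r) + 1L
    on <- runValue(r)
    if (!any(on)) next
    ir <- IRanges(starts[on], ends[on])                  # bin space
    ir <- reduce(ir, min.gapwidth = mergeGapBins + 1L)
    ir <- ir[width(ir) >= minBins]
    if (length(ir) == 0L) next
    res[[ch]] <- GRanges(ch, IRanges((start(ir) - 1L) * binSize + 1L,
                                     pmin(end(ir) * binSize, chromSizes[[ch]])),
                         seqlengths = chromSizes)
  }
  if (length(res) == 0L) {
    gr <- GRanges()
    seqlevels(gr) <- names(chromSizes)
    seqlengths(gr) <- chromSizes
    return(gr)
  }
  gr <- sort(do.call(c, unname(res)))
  seqlevels(gr) <- names(chromSizes)
  seqlengths(gr) <- chromSizes
  gr
}

#' Call R-loop peaks from DRIP-seq coverage
#'
#' End-to-end peak calling: pool replicate tracks (default, mirroring combined
#' multi-sample signal) or call per replicate and keep regions supported by at
#' least `k` replicates, then bin, fit the two-state HMM, decode and
#' post-process.
#'
#' @param tracks A single `RleList` or a list of them (replicates).
#' @param chromSizes Named chromosome lengths.
#' @param binSize Bin width in bp.
#' @param minBins,mergeGapBins Post-processing parameters, see [callPeaks].
#' @param mode `"pooled"` (default) or `"intersect"` (k-of-n replicate
#'   support).
#' @param k Minimum replicate support in `"intersect"` mode.
#' @return A `GRanges` of peaks; the fitted model, bin size and mode are kept
#'   in `S4Vectors::metadata()`.
#' @export
callRloopPeaks <- function(tracks, chromSizes, binSize = 500L, minBins = 3L,
                           mergeGapBins = 1L, mode = c("pooled", "intersect"),
                           k = 1L) {
  mode <- match.arg(mode)
  if (!is.list(tracks)) tracks <- list(tracks)
  one <- function(track) {
    binned <- binCoverage(track, binSize, chromSizes)
    model <- fitPeakHmm(binned)
    peaks <- callPeaks(viterbiPeaks(model, binned), binSize, chromSizes,
                       minBins, mergeGapBins)
    list(peaks = peaks, model = model)
  }
  if (mode == "pooled") {
    fit <- one(poolTracks(tracks))
    peaks <- fit$peaks
    model <- fit$model
  } else {
    calls <- lapply(tracks, one)
    cov <- GenomicRanges::coverage(do.call(c, lapply(calls, `[[`, "peaks")))
    peaks <- GRanges(IRanges::slice(cov, lower = k, rangesOnly = TRUE))
    seqlevels(peaks) <- names(chromSizes)
    seqlengths(peaks) <- chromSizes
    peaks <- sort(peaks)
    model <- calls[[1]]$model
  }
  S4Vectors::metadata(peaks) <- list(model = model, bin_size = binSize,
                                     min_bins = minBins,
                                     merge_gap_bins = mergeGapBins,
                                     mode = mode, n_tracks = length(tracks))
  peaks
}
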