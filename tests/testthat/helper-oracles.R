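# Independent oracles used across the suite. These deliberately use naive
# enumeration / direct counting, never the package's own code paths.

# Exhaustive Viterbi: maximal joint log-probability over all k^n state paths.
bruteViterbiLogp <- function(logEmis, logTrans, logInit) {
  n <- nrow(logEmis); k <- ncol(logEmis)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- -Inf
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    lp <- logInit[p[1]] + logEmis[1, p[1]]
    if (n > 1) for (t in 2:n)
      lp <- lp + logTrans[p[t - 1], p[t]] + logEmis[t, p[t]]
    if (lp > best) best <- lp
  }
  best
}

# Exact two-sided Mann-Whitney p by enumeration of all group labelings:
# the proportion of labelings whose U deviates from the null mean at least
# as much as the observed U.
mwEnumerationP <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  uOf <- function(ix) {
    xx <- pool[ix]; yy <- pool[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  uObs <- uOf(seq_len(n1))
  mid <- n1 * n2 / 2
  labelings <- utils::combn(n1 + n2, n1)
  devs <- apply(labelings, 2, function(ix) abs(uOf(ix) - mid))
  mean(devs >= abs(uObs - mid) - 1e-12)
}

# Step-up BH by direct formula on sorted p-values.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Hypergeometric upper tail by explicit binomial-coefficient summation.
hyperTailOracle <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Per-bp weighted median by brute expansion.
weightedMedianOracle <- function(values, weights) {
  v <- rep(values, weights)
  v <- sort(v)
  n <- length(v)
  if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
}

# A tiny deterministic gene universe on one chromosome for interval tests.
tinyGeneModels <- function() {
  genes <- GenomicRanges::GRanges(
    "chrT",
    IRanges::IRanges(c(3001, 12001, 30001), c(9000, 20000, 36000)),
    strand = c("+", "-", "+"),
    gene_id = c("gA", "gB", "gC"))
  GenomeInfoDb::seqlengths(genes) <- c(chrT = 50000L)
  exons <- GenomicRanges::GRangesList(
    gA = GenomicRanges::GRanges("chrT", IRanges::IRanges(c(3001, 7001),
                                                         c(4000, 9000))),
    gB = GenomicRanges::GRanges("chrT", IRanges::IRanges(c(12001, 18001),
                                                         c(14000, 20000))),
    gC = GenomicRanges::GRanges("chrT", IRanges::IRanges(30001, 36000)))
  GeneModels(genes, exons)
}

# Small, fast simulation shared by tests (cached per session).
.sim_cache <- new.env(parent = emptyenv())
sharedSim <- function() {
  if (is.null(.sim_cache$sim))
    .sim_cache$sim <- simulateRloopData(simConfig(seed = 11L))
  .sim_cache$sim
}

# Random non-overlapping gene set on a small genome (for partition tests).
randomGeneModels <- function(nGenes, chromLen = c(chrR = 200000L)) {
  lens <- sample(500:4000, nGenes, replace = TRUE)
  gaps <- sample(100:2000, nGenes + 1, replace = TRUE)
  needed <- sum(lens) + sum(gaps)
  stopifnot(needed <= chromLen[[1]])
  starts <- cumsum(gaps)[seq_len(nGenes)] + cumsum(c(0, lens))[seq_len(nGenes)]
  genes <- GenomicRanges::GRanges(
    names(chromLen), IRanges::IRanges(starts + 1L, starts + lens),
    strand = sample(c("+", "-"), nGenes, TRUE),
    gene_id = sprintf("r%03d", seq_len(nGenes)))
  GenomeInfoDb::seqlengths(genes) <- chromLen
  GeneModels(genes)
}
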