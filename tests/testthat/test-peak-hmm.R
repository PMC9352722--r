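test_that("binCoverage averages over bp spans including partial bins", {
  tr <- as(list(chr1 = Rle(1, 1000)), "RleList")
  b <- binCoverage(tr, 100, c(chr1 = 1000L))
  expect_equal(b$bins$chr1, rep(1, 10))
  # value 2 over the first 50 bp of a 100-bp bin averages to 1
  tr2 <- as(list(chr1 = Rle(c(2, 0), c(50, 950))), "RleList")
  expect_equal(binCoverage(tr2, 100, c(chr1 = 1000L))$bins$chr1[1], 1)
  # empty track: all-zero bins; trailing partial bin counted
  tr3 <- as(list(chr1 = Rle(0, 250)), "RleList")
  b3 <- binCoverage(tr3, 100, c(chr1 = 250L))
  expect_equal(b3$bins$chr1, c(0, 0, 0))
  expect_error(binCoverage(tr, 0, c(chr1 = 1000L)), "binSize")
})

test_that("poolTracks adds coverage position-wise", {
  a <- as(list(chr1 = Rle(1, 100)), "RleList")
  b <- as(list(chr1 = Rle(2, 100)), "RleList")
  z <- as(list(chr1 = Rle(0, 100)), "RleList")
  expect_equal(as.numeric(poolTracks(list(a))$chr1), rep(1, 100))
  expect_equal(as.numeric(poolTracks(list(a, z))$chr1), rep(1, 100))
  expect_equal(as.numeric(poolTracks(list(a, b))$chr1), rep(3, 100))
  other <- as(list(chr2 = Rle(1, 100)), "RleList")
  expect_error(poolTracks(list(a, other)), "universe")
})

test_that("Viterbi equals brute-force enumeration on short bin paths", {
  set.seed(42)
  for (rep in 1:12) {
    n <- sample(2:10, 1)
    mu <- sort(rnorm(2, c(0, 2), 0.5))
    sigma <- runif(2, 0.2, 1)
    a <- runif(1, 0.05, 0.95); b <- runif(1, 0.05, 0.95)
    model <- PeakHmm(init = c(0.7, 0.3),
                     trans = matrix(c(a, 1 - a, 1 - b, b), 2, byrow = TRUE),
                     mu = mu, sigma = sigma)
    x <- pmax(rnorm(n, sample(mu, n, replace = TRUE), 0.5), 0)
    binned <- structure(list(bins = list(chrZ = x), bin_size = 10L,
                             chrom_sizes = c(chrZ = 10L * n)),
                        class = "BinnedTrack")
    path <- viterbiPeaks(model, binned)$chrZ
    le <- cbind(dnorm(log1p(x), mu[1], sigma[1], log = TRUE),
                dnorm(log1p(x), mu[2], sigma[2], log = TRUE))
    lp <- sum(log(model@init)[path[1]], le[1, path[1]],
              if (n > 1) vapply(2:n, function(t)
                log(model@trans)[path[t - 1], path[t]] + le[t, path[t]], 0))
    expect_equal(lp, bruteViterbiLogp(le, log(model@trans), log(model@init)),
                 tolerance = 1e-10)
  }
})

test_that("Viterbi ties resolve toward background", {
  model <- PeakHmm(init = c(0.5, 0.5),
                   trans = matrix(0.5, 2, 2),
                   mu = c(1, 1), sigma = c(1, 1))
  binned <- structure(list(bins = list(c1 = abs(rnorm(20))), bin_size = 10L,
                           chrom_sizes = c(c1 = 200L)),
                      class = "BinnedTrack")
  expect_true(all(viterbiPeaks(model, binned)$c1 == 1L))
})

test_that("Baum-Welch log-likelihood is monotone and recovers planted emissions", {
  set.seed(7)
  states <- rep(rep(1:2, 25), times = 1)
  states <- rep(states, each = 20)   # blocks of 20 bins
  x <- expm1(rnorm(length(states), c(0, 3)[states], 0.3))
  x[x < 0] <- 0
  binned <- structure(list(bins = list(c1 = x), bin_size = 10L,
                           chrom_sizes = c(c1 = 10L * length(x))),
                      class = "BinnedTrack")
  fit <- fitPeakHmm(binned)
  expect_true(all(diff(fit@loglik) > -1e-8))
  expect_lt(abs(fit@mu[1] - 0), 0.2)
  expect_lt(abs(fit@mu[2] - 3), 0.2)
  expect_gte(fit@mu[2], fit@mu[1])   # relabeling contract
})

test_that("Baum-Welch rejects degenerate constant input", {
  binned <- structure(list(bins = list(c1 = rep(2, 50)), bin_size = 10L,
                           chrom_sizes = c(c1 = 500L)),
                      class = "BinnedTrack")
  expect_error(fitPeakHmm(binned), "degenerate")
})

test_that("callPeaks applies run, merge and minimum-length rules", {
  cs <- c(c1 = 1000L)
  # enriched run of 2 bins with minBins 2: peak spans bins 3-4
  p <- callPeaks(list(c1 = c(1L, 1L, 2L, 2L, 1L)), 100, cs, minBins = 2)
  expect_equal(start(p), 201L)
  expect_equal(end(p), 400L)        # 0-based [200, 400)
  # all background
  expect_length(callPeaks(list(c1 = rep(1L, 5)), 100, cs), 0)
  # two runs separated by one background bin merge with mergeGapBins = 1
  p2 <- callPeaks(list(c1 = c(2L, 2L, 1L, 2L, 2L)), 100, cs,
                  minBins = 3, mergeGapBins = 1)
  expect_length(p2, 1)
  expect_equal(width(p2), 500L)
  # without gap bridging the two short runs are dropped by minBins = 3
  p3 <- callPeaks(list(c1 = c(2L, 2L, 1L, 2L, 2L)), 100, cs,
                  minBins = 3, mergeGapBins = 0)
  expect_length(p3, 0)
})

test_that("called peaks are sorted, non-overlapping and long enough", {
  set.seed(5)
  path <- sample(1:2, 400, replace = TRUE, prob = c(0.8, 0.2))
  p <- callPeaks(list(c1 = path[1:200], c2 = path[201:400]), 50,
                 c(c1 = 10000L, c2 = 10000L), minBins = 3, mergeGapBins = 1)
  expect_true(all(width(p) >= 150))
  expect_identical(p, sort(p))
  expect_true(all(countOverlaps(p, p) == 1))
})

test_that("peak calling on well-separated signal recovers the planted blocks", {
  set.seed(99)
  truth <- rep(c(1, 2, 1, 2, 1), c(100, 20, 150, 30, 100))
  x <- rpois(length(truth), c(0.3, 4)[truth])
  tr <- as(list(c1 = Rle(as.numeric(rep(x, each = 10)))), "RleList")
  cs <- c(c1 = length(truth) * 10L)
  peaks <- callRloopPeaks(tr, cs, binSize = 10L, minBins = 3L)
  planted <- GRanges("c1", IRanges(c(1001, 2701), c(1200, 3000)))
  rec <- peakRecovery(planted, peaks)
  expect_gte(rec$fraction_recovered, 0.99)
})
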