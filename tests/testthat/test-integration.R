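test_that("promoterGC matches a direct base-counting oracle", {
  set.seed(4)
  bases <- sample(c("A", "C", "G", "T"), 10000, TRUE)
  genome <- Biostrings::DNAStringSet(c(chrP = paste(bases, collapse = "")))
  genes <- GRanges("chrP", IRanges(4001, 8000), strand = "+", gene_id = "g")
  seqlengths(genes) <- c(chrP = 10000L)
  gm <- GeneModels(genes)
  got <- unname(promoterGC(gm, genome, 2000))
  win <- bases[2001:6001]            # TSS 4001 +/- 2000
  expect_equal(got, mean(win %in% c("G", "C")))
  # all-G and alternating promoters
  gAll <- Biostrings::DNAStringSet(c(chrP = strrep("G", 10000)))
  expect_equal(unname(promoterGC(gm, gAll, 2000)), 1)
  gAlt <- Biostrings::DNAStringSet(c(chrP = strrep("ACGT", 2500)))
  # 4001-bp window: 1000 ACGT repeats (2000 G+C) plus one leading A
  expect_equal(unname(promoterGC(gm, gAlt, 2000)), 2000 / 4001)
})

test_that("peaks are assigned to promoter-extended gene spans", {
  gm <- tinyGeneModels()
  inside <- GRanges("chrT", IRanges(5000, 5100))      # inside gA only
  desert <- GRanges("chrT", IRanges(45000, 45100))
  promo <- GRanges("chrT", IRanges(1200, 1300))       # 2 kb upstream of gA
  a <- assignPeaksToGenes(c(inside, desert, promo), gm)
  expect_equal(a$gA, c(1L, 3L))
  expect_length(a$gB, 0)
  # bodyOnly drops the promoter-window peak
  b <- assignPeaksToGenes(c(inside, desert, promo), gm, bodyOnly = TRUE)
  expect_equal(b$gA, 1L)
  # a peak spanning two genes serves both
  genes2 <- GRanges("chrT", IRanges(c(1000, 1800), c(2000, 3000)),
                    strand = "+", gene_id = c("o1", "o2"))
  seqlengths(genes2) <- c(chrT = 50000L)
  both <- assignPeaksToGenes(GRanges("chrT", IRanges(1900, 1950)),
                             GeneModels(genes2), promoterHalfwidth = 10)
  expect_equal(lengths(both), c(o1 = 1L, o2 = 1L))
})

test_that("peak density is count per kb", {
  expect_equal(peakDensity(2, 10000), 0.2)
  expect_equal(peakDensity(0, 10000), 0)
  expect_equal(peakDensity(2, 5000), 2 * peakDensity(2, 10000))
  expect_error(peakDensity(1, 0), "length")
})

test_that("junction proximity counts a junction iff a peak is within the window", {
  peaks <- GRanges("chr1", IRanges(10001, 10600))
  # overlap, exactly window away, window + 1 away
  j <- GRanges("chr1", IRanges(c(10300, 8001, 8000), width = 1))
  r <- junctionPeakProximity(j, peaks, window = 2000)
  expect_equal(r$n_within, 2L)
  expect_equal(r$n_total, 3L)
  expect_error(junctionPeakProximity(GRanges(), peaks), "empty")
  allIn <- junctionPeakProximity(
    GRanges("chr1", IRanges(c(10100, 10500), width = 1)), peaks)
  expect_equal(allIn$fraction, 1)
})

test_that("junction proximity agrees with a brute-force all-pairs oracle", {
  set.seed(12)
  for (rep in 1:5) {
    peaks <- GRanges("c1", IRanges(sort(sample(100000, 30)), width = 500))
    j <- GRanges("c1", IRanges(sample(100000, 80), width = 1))
    w <- sample(c(0, 500, 2000), 1)
    got <- junctionPeakProximity(j, peaks, w)$n_within
    # oracle: a junction at p is within w of peak [s,e] iff s - w <= p <= e + w
    oracle <- sum(vapply(start(j), function(p)
      any(start(peaks) - w <= p & p <= end(peaks) + w), TRUE))
    expect_equal(got, oracle)
  }
})

test_that("peaksNearJunctionsPerGene counts peaks, not junction-peak pairs", {
  peaks <- GRanges("c1", IRanges(5000, 5600))
  j <- GRanges("c1", IRanges(c(4500, 5200, 6100, 50000), width = 1),
               gene_id = c("g1", "g1", "g1", "g2"))
  out <- peaksNearJunctionsPerGene(peaks, j, c("g1", "g2", "g3"))
  expect_equal(out, c(g1 = 1L, g2 = 0L, g3 = 0L))
})

test_that("interval timing is the bp-weighted median, NA when unreported", {
  tr <- as(list(c1 = Rle(c(1.5, NA), c(1000, 1000))), "RleList")
  expect_equal(intervalTiming(GRanges("c1", IRanges(1, 500)), tr), 1.5)
  expect_true(is.na(suppressMessages(
    intervalTiming(GRanges("c1", IRanges(1500, 1600)), tr))))
  # equal-weight values 1 and 3 -> 2
  tr2 <- as(list(c1 = Rle(c(1, 3), c(100, 100))), "RleList")
  expect_equal(intervalTiming(GRanges("c1", IRanges(1, 200)), tr2), 2)
  # random weighted medians vs brute bp expansion
  set.seed(77)
  for (rep in 1:8) {
    vals <- sample(-5:5, 4)
    lens <- sample(1:50, 4, replace = TRUE)
    tr3 <- as(list(c1 = Rle(as.numeric(vals), lens)), "RleList")
    got <- intervalTiming(GRanges("c1", IRanges(1, sum(lens))), tr3)
    expect_equal(got, weightedMedianOracle(vals, lens))
  }
})

test_that("common/unique gene sets follow Venn arithmetic", {
  v <- commonUniqueGeneSets(c("g1", "g2"), c("g2", "g3"))
  expect_equal(v$common, "g2")
  expect_equal(v$unique_a, "g1")
  expect_equal(v$unique_b, "g3")
  same <- commonUniqueGeneSets(c("a", "b"), c("a", "b"))
  expect_length(same$unique_a, 0)
  expect_equal(same$pct_common_of_a, 100)
  set.seed(9)
  for (rep in 1:5) {
    a <- sample(letters, sample(5:20, 1))
    b <- sample(letters, sample(5:20, 1))
    v <- commonUniqueGeneSets(a, b)
    expect_equal(length(v$common) + length(v$unique_a), length(unique(a)))
    expect_equal(length(v$common) + length(v$unique_b), length(unique(b)))
  }
})

test_that("down-sampling is exact-size, deterministic and uniform", {
  peaks <- GRanges("c1", IRanges(seq(1, 10000, by = 100), width = 50))
  expect_identical(downsamplePeaks(peaks, length(peaks), 1), sort(peaks))
  expect_length(downsamplePeaks(peaks, 0, 1), 0)
  expect_identical(downsamplePeaks(peaks, 10, 42), downsamplePeaks(peaks, 10, 42))
  expect_error(downsamplePeaks(peaks, length(peaks) + 1, 1), "between")
  # inclusion frequency ~ k/n within a binomial band
  hits <- integer(length(peaks))
  for (s in 1:200) {
    idx <- match(start(downsamplePeaks(peaks, 30, s)), start(peaks))
    hits[idx] <- hits[idx] + 1
  }
  pHat <- hits / 200
  expect_true(all(abs(pHat - 0.3) < 4 * sqrt(0.3 * 0.7 / 200)))
})

test_that("metagene profiles are flat on constant tracks and strand-symmetric", {
  cs <- c(cM = 40000L)
  tr <- as(list(cM = Rle(2, 40000)), "RleList")
  genes <- GRanges("cM", IRanges(10001, 20000), strand = "+", gene_id = "g")
  seqlengths(genes) <- cs
  prof <- metageneProfile(tr, GeneModels(genes))
  expect_equal(prof, rep(2, 140))
  # delta signal at the TSS peaks at the first body bin
  tr2 <- as(list(cM = Rle(c(0, 5, 0), c(10000, 100, 29900))), "RleList")
  prof2 <- metageneProfile(tr2, GeneModels(genes))
  expect_equal(which.max(prof2), 21)
  # mirrored minus-strand gene yields the identical profile
  sig <- c(rep(0, 12000), rep(3, 500), rep(0, 27500))
  trP <- as(list(cM = Rle(sig)), "RleList")
  trM <- as(list(cM = Rle(rev(sig))), "RleList")
  gP <- GeneModels(genes)
  genesM <- GRanges("cM", IRanges(40000 - 20000 + 1, 40000 - 10001 + 1),
                    strand = "-", gene_id = "g")
  seqlengths(genesM) <- cs
  gM <- GeneModels(genesM)
  expect_equal(metageneProfile(trP, gP), metageneProfile(trM, gM))
})

test_that("TSS profiles center the start site and respect strand", {
  cs <- c(cM = 40000L)
  genes <- GRanges("cM", IRanges(10001, 20000), strand = "+", gene_id = "g")
  seqlengths(genes) <- cs
  flat <- as(list(cM = Rle(1, 40000)), "RleList")
  expect_equal(tssProfile(flat, GeneModels(genes)), rep(1, 80))
  delta <- as(list(cM = Rle(c(0, 9, 0), c(10000, 10, 29990))), "RleList")
  prof <- tssProfile(delta, GeneModels(genes))
  expect_equal(which.max(prof), 41)   # first bin downstream of the TSS
  sig <- c(rep(0, 10200), rep(4, 100), rep(0, 29700))
  trP <- as(list(cM = Rle(sig)), "RleList")
  trM <- as(list(cM = Rle(rev(sig))), "RleList")
  genesM <- GRanges("cM", IRanges(40000 - 20000 + 1, 40000 - 10001 + 1),
                    strand = "-", gene_id = "g")
  seqlengths(genesM) <- cs
  expect_equal(tssProfile(trP, GeneModels(genes)),
               tssProfile(trM, GeneModels(genesM)))
})

test_that("gene stats table is internally consistent and idempotent", {
  sim <- sharedSim()
  expr <- expressionTable(sim$genes, sim$gro,
                          librarySize = sim$config$library_size)
  s1 <- geneStatsTable(sim$genes, sim$peaks, expr,
                       timing = sim$timing, rdcJunctions = sim$junctions_rdc,
                       tssJunctions = sim$junctions_tss,
                       config = analysisConfig(bin_size = 100))
  expect_equal(s1$peak_density, s1$peak_count / (s1$length / 1000))
  s2 <- geneStatsTable(sim$genes, sim$peaks, expr,
                       timing = sim$timing, rdcJunctions = sim$junctions_rdc,
                       tssJunctions = sim$junctions_tss,
                       config = analysisConfig(bin_size = 100))
  expect_identical(s1, s2)
  expect_equal(sum(s1$is_rdc), 10)
})
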