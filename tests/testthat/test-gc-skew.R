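test_that("sequence Viterbi equals brute-force enumeration for short sequences", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    # random valid 4-state model (STRONG keeps max G-C margin, REVERSE mirror)
    emis <- rbind(NONE = rep(0.25, 4),
                  STRONG = c(0.15, 0.15, 0.55, 0.15),
                  WEAK = c(0.25, 0.2, 0.3, 0.25),
                  REVERSE = c(0.15, 0.55, 0.15, 0.15))
    self <- runif(1, 0.6, 0.99)
    model <- skewHmm("stringent", emis = emis, selfTransition = self)
    seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    path <- as.character(viterbiSequence(model, seq))
    idx <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
    le <- t(log(model@emis))[idx, , drop = FALSE]
    st <- match(path, model@states)
    lp <- log(0.25) + le[1, st[1]]
    if (n > 1) for (t in 2:n)
      lp <- lp + log(model@trans)[st[t - 1], st[t]] + le[t, st[t]]
    expect_equal(lp, bruteViterbiLogp(le, log(model@trans), log(rep(0.25, 4))),
                 tolerance = 1e-10)
  }
})

test_that("a long G homopolymer decodes all-STRONG under the stringent model", {
  path <- viterbiSequence(skewHmm("stringent"), strrep("G", 200))
  expect_equal(unique(as.character(path)), "STRONG")
})

test_that("identical emissions across states decode to all-NONE (tie-break)", {
  emis <- matrix(0.25, 4, 4,
                 dimnames = list(c("NONE", "STRONG", "WEAK", "REVERSE"),
                                 c("A", "C", "G", "T")))
  # bypass the STRONG/REVERSE margin validity checks: construct directly
  model <- skewHmm("stringent")
  model@emis <- emis
  path <- viterbiSequence(model, "ACGTACGTAC")
  expect_equal(unique(as.character(path)), "NONE")
})

test_that("empty or invalid sequences are rejected", {
  expect_error(viterbiSequence(skewHmm(), ""), "empty")
  expect_error(viterbiSequence(skewHmm(), "ACGX"), "outside")
})

test_that("N bases are emission-neutral", {
  m <- skewHmm("stringent")
  withN <- as.character(viterbiSequence(m, paste0(strrep("G", 100), "NNNN",
                                                  strrep("G", 100))))
  expect_equal(unique(withN), "STRONG")
})

test_that("segmentsFromPath run-length encodes into a partition", {
  p <- Rle(factor(c("STRONG", "STRONG", "NONE", "NONE", "REVERSE"),
                  levels = c("NONE", "STRONG", "WEAK", "REVERSE")))
  seg <- segmentsFromPath(p, "chr1")
  expect_length(seg, 3)
  expect_equal(mcols(seg)$state, c("STRONG", "NONE", "REVERSE"))
  expect_equal(sum(width(seg)), 5)
  expect_true(all(mcols(seg)$state[-1] != mcols(seg)$state[-length(seg)]))
  one <- segmentsFromPath(Rle(rep("NONE", 10)), "chr1")
  expect_length(one, 1)
})

test_that("reverse-complement decoding swaps STRONG and REVERSE", {
  # mirror-symmetric model: WEAK has P(A)=P(T), P(C)=P(G) so the complement
  # operation maps STRONG<->REVERSE and fixes WEAK/NONE
  emis <- rbind(NONE = rep(0.25, 4),
                STRONG = c(0.20, 0.20, 0.40, 0.20),
                WEAK = c(0.30, 0.20, 0.20, 0.30),
                REVERSE = c(0.20, 0.40, 0.20, 0.20))
  model <- skewHmm("lenient", emis = emis, selfTransition = 1 - 1 / 50)
  set.seed(3)
  seq <- paste(c(sample(c("A", "C", "G", "T"), 300, TRUE,
                        prob = c(0.2, 0.2, 0.4, 0.2)),   # STRONG block
                 sample(c("A", "C", "G", "T"), 300, TRUE),
                 sample(c("A", "C", "G", "T"), 300, TRUE,
                        prob = c(0.2, 0.4, 0.2, 0.2))),  # REVERSE block
               collapse = "")
  fwd <- as.character(viterbiSequence(model, seq))
  rcp <- as.character(viterbiSequence(
    model, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))))
  swap <- c(NONE = "NONE", STRONG = "REVERSE", WEAK = "WEAK",
            REVERSE = "STRONG")
  expect_equal(rev(unname(swap[rcp])), fwd)
})

test_that("gene skew classification applies the state priority at the promoter", {
  gm <- tinyGeneModels()[1]          # gA: + strand at 3001-9000, TSS 3001
  segs <- list(
    forward = GRanges("chrT", IRanges(c(1, 2001, 4001), c(2000, 4000, 50000)),
                      state = c("WEAK", "STRONG", "NONE")),
    reverse = GRanges("chrT", IRanges(1, 50000), state = "NONE"))
  expect_equal(unname(classifyGeneSkew(gm, segs)), "strong")
  # without the STRONG segment the WEAK overlap wins over NONE
  segs$forward <- GRanges("chrT", IRanges(c(1, 2001), c(2000, 50000)),
                          state = c("WEAK", "NONE"))
  expect_equal(unname(classifyGeneSkew(gm, segs)), "weak")
  segs$forward <- GRanges("chrT", IRanges(1, 50000), state = "NONE")
  expect_equal(unname(classifyGeneSkew(gm, segs)), "none")
  expect_error(classifyGeneSkew(gm, list(
    forward = GRanges("chrX", IRanges(1, 10), state = "NONE"),
    reverse = GRanges("chrX", IRanges(1, 10), state = "NONE"))), "absent")
})

test_that("a minus-strand gene with G-rich coding strand classifies strong", {
  # gene on minus strand: coding (non-template) strand G-rich means the
  # forward genomic strand is C-rich over the promoter
  L <- 20000L
  set.seed(8)
  bases <- sample(c("A", "C", "G", "T"), L, TRUE)
  tssPos <- 12000L                   # minus-strand TSS at gene end
  win <- (tssPos - 2000):(tssPos + 2000)
  bases[win] <- sample(c("A", "C", "G", "T"), length(win), TRUE,
                       prob = c(0.2, 0.4, 0.2, 0.2))  # C-rich forward
  genome <- Biostrings::DNAStringSet(c(chrM = paste(bases, collapse = "")))
  genes <- GRanges("chrM", IRanges(4000, tssPos), strand = "-",
                   gene_id = "gMinus")
  seqlengths(genes) <- c(chrM = L)
  gm <- GeneModels(genes)
  segs <- skewSegmentsGenome(genome, skewHmm("stringent"))
  expect_equal(unname(classifyGeneSkew(gm, segs)), "strong")
})

test_that("skewProfile computes windowed (G-C)/(G+C) with degenerate flagging", {
  p <- skewProfile(strrep("G", 100), 100)
  expect_equal(p$skew, 1)
  p2 <- skewProfile(strrep("GC", 50), 100)
  expect_equal(p2$skew, 0)
  expect_false(p2$undefined)
  p3 <- skewProfile(strrep("AT", 50), 100)
  expect_equal(p3$skew, 0)
  expect_true(p3$undefined)
  expect_error(skewProfile("ACGT", 0), "window")
})
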