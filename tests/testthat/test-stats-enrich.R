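test_that("Mann-Whitney U: worked example and U + U' identity", {
  r <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 2 / 6, tolerance = 1e-12)
  expect_true(r$exact)
  # identical multisets: U = n1 n2 / 2 (via statistic symmetry)
  r2 <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$statistic, 4.5)
})

test_that("exact Mann-Whitney agrees with enumeration for all sizes up to 12", {
  set.seed(10)
  for (n1 in 1:6) for (n2 in n1:(12 - n1)) {
    x <- sample(seq(1, 400), n1)
    y <- sample(setdiff(seq(1, 400), x), n2)
    r <- mannWhitneyU(x, y)
    expect_true(r$exact)
    expect_equal(r$p_value, mwEnumerationP(x, y), tolerance = 1e-10,
                 label = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("the normal approximation tracks the exact p for moderate sizes", {
  set.seed(20)
  for (rep in 1:5) {
    x <- sample(1000, 8); y <- sample(setdiff(1:1000, x), 8)
    pApprox <- mannWhitneyU(x, y, exactLimit = 0L)$p_value
    expect_lt(abs(pApprox - mwEnumerationP(x, y)), 0.02)
  }
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  r <- oneWayAnova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$statistic, 13.5)    # MSB = 13.5, MSW = 1
  expect_equal(r$p_value, stats::pf(13.5, 1, 4, lower.tail = FALSE))
  # identical groups: F = 0, p = 1
  r0 <- oneWayAnova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # jointly permuting observations within groups leaves F unchanged
  r1 <- oneWayAnova(list(c(3, 1, 2), c(6, 4, 5)))
  expect_equal(r1$statistic, r$statistic)
  expect_error(oneWayAnova(list(1:3)), "2 groups")
  expect_error(oneWayAnova(list(c(1, 1), c(1, 1))), "degenerate")
})

test_that("Tukey HSD reduces to the equal-variance t-test for two groups", {
  set.seed(30)
  a <- rnorm(6); b <- rnorm(6, 1)
  tk <- tukeyHsd(list(A = a, B = b))
  tt <- stats::t.test(a, b, var.equal = TRUE)$p.value
  expect_equal(tk$p_adj, tt, tolerance = 1e-6)   # q = t * sqrt(2) identity
  # identical groups: adjusted p ~ 1
  tkSame <- tukeyHsd(list(A = c(1, 2, 3), B = c(1, 2, 3) + 1e-9))
  expect_gt(tkSame$p_adj, 0.999)
})

test_that("Tukey-adjusted p-values dominate unadjusted pairwise p-values", {
  set.seed(31)
  groups <- list(a = rnorm(5), b = rnorm(5, 0.5), c = rnorm(5, 1))
  tk <- tukeyHsd(groups)
  pooledDf <- sum(lengths(groups)) - length(groups)
  s2 <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / pooledDf
  pairs <- utils::combn(names(groups), 2)
  for (i in seq_len(ncol(pairs))) {
    g1 <- groups[[pairs[1, i]]]; g2 <- groups[[pairs[2, i]]]
    tstat <- (mean(g1) - mean(g2)) /
      sqrt(s2 * (1 / length(g1) + 1 / length(g2)))
    pUnadj <- 2 * stats::pt(abs(tstat), pooledDf, lower.tail = FALSE)
    row <- grepl(pairs[1, i], tk$comparison) & grepl(pairs[2, i], tk$comparison)
    expect_gte(tk$p_adj[row] + 1e-12, pUnadj)
  }
})

test_that("hypergeometric enrichment matches combinatorial oracles", {
  uni <- sprintf("u%02d", 1:20)
  term <- uni[1:5]
  lst <- uni[1:4]
  r <- hypergeometricEnrichment(lst, term, uni)
  expect_equal(r$p_value, 5 / 4845, tolerance = 1e-12)  # C(5,4)/C(20,4)
  expect_equal(r$p_value, hyperTailOracle(4, 5, 20, 4), tolerance = 1e-12)
  # k = 0 -> p = 1
  r0 <- hypergeometricEnrichment(uni[6:9], uni[10:12], uni)
  expect_equal(r0$p_value, 1)
  # proportional overlap -> factor exactly 1
  r1 <- hypergeometricEnrichment(uni[1:4], c(uni[1], uni[5:8]), uni)
  expect_equal(r1$enrichment_factor, 1)
  expect_error(hypergeometricEnrichment(c("zz"), term, uni), "universe")
  # random-case agreement with the explicit summation oracle
  set.seed(40)
  for (rep in 1:10) {
    K <- sample(3:10, 1); n <- sample(3:10, 1)
    term <- sample(uni, K); lst <- sample(uni, n)
    r <- hypergeometricEnrichment(lst, term, uni)
    expect_equal(r$p_value, hyperTailOracle(r$k, K, 20, n), tolerance = 1e-12)
  }
})

test_that("BH q-values follow the step-up formula", {
  expect_equal(bhFdr(0.02), 0.02)
  expect_equal(bhFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bhFdr(c(0.5, 1.2)), "between 0 and 1")
  set.seed(50)
  p <- runif(40)^2
  q <- bhFdr(p)
  expect_equal(q, bhOracle(p))
  # thresholding q <= alpha rejects exactly the step-up set
  for (alpha in c(0.05, 0.2)) {
    ps <- sort(p)
    kk <- which(ps <= alpha * seq_along(ps) / length(ps))
    stepUp <- if (length(kk)) sum(p <= ps[max(kk)]) else 0L
    expect_equal(sum(q <= alpha), stepUp)
  }
})

test_that("Cohen's kappa and term clustering behave on archetypal cases", {
  bg <- sprintf("g%03d", 1:100)
  expect_equal(cohenKappa(bg[1:10], bg[1:10], bg), 1)
  expect_lte(cohenKappa(bg[1:10], bg[11:20], bg), 0)
  # kappa formula oracle on the 2x2 table for disjoint equal sets
  a <- bg %in% bg[1:10]; b <- bg %in% bg[11:20]
  po <- mean(a == b); pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  expect_equal(cohenKappa(bg[1:10], bg[11:20], bg), (po - pe) / (1 - pe))
})

test_that("term filtering and kappa clustering apply the documented thresholds", {
  mk <- function(term, k, p, factor, genes)
    data.frame(term = term, k = k, n = 20, K = 30, N = 200, p_value = p,
               enrichment_factor = factor, q_value = p,
               genes = I(list(genes)), stringsAsFactors = FALSE)
  bg <- sprintf("g%03d", 1:40)
  recs <- rbind(mk("same1", 10, 1e-6, 3, bg[1:10]),
                mk("same2", 10, 1e-5, 3, bg[1:10]),
                mk("other", 10, 1e-4, 3, bg[21:30]),
                mk("lowK", 2, 1e-6, 3, bg[1:2]),        # fails min count
                mk("weak", 10, 0.5, 3, bg[5:14]),       # fails p < 0.01
                mk("flat", 10, 1e-6, 1.2, bg[11:20]))   # fails factor > 1.5
  out <- filterAndClusterTerms(recs)
  expect_setequal(out$term, c("same1", "same2", "other"))
  expect_equal(out$cluster[out$term == "same1"],
               out$cluster[out$term == "same2"])
  expect_false(out$cluster[out$term == "other"] ==
                 out$cluster[out$term == "same1"])
  # identical gene sets share the smallest-p representative
  expect_equal(unique(out$representative[out$term %in% c("same1", "same2")]),
               "same1")
  expect_message(filterAndClusterTerms(recs[recs$term == "lowK", ]),
                 "no terms survive")
})

test_that("planted enriched terms rank top across repeated simulations", {
  set.seed(60)
  top <- logical(20)
  for (rep in 1:20) {
    universe <- sprintf("g%03d", 1:200)
    special <- sample(universe, 60)
    sets <- c(lapply(1:3, function(i)
      c(sample(special, 24), sample(setdiff(universe, special), 6))),
      lapply(1:15, function(i) sample(universe, 30)))
    names(sets) <- c(sprintf("planted%02d", 1:3), sprintf("bg%02d", 1:15))
    enr <- enrichGeneSets(special, sets, universe)
    top3 <- enr$term[order(enr$p_value)][1:3]
    top[rep] <- all(grepl("^planted", top3))
  }
  expect_gte(mean(top), 0.95)
})
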