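#' Two-sided Mann-Whitney U test
#'
#' Exact p-value by enumeration (via the exact null distribution) when the
#' combined sample size is at most `exactLimit` and the data carry no ties;
#' otherwise the normal approximation with tie and continuity corrections.
#' U (for `x`) plus U' (for `y`) always equals |x| * |y|.
#'
#' @param x,y Non-empty numeric samples.
#' @param exactLimit Combined-size switchover to the approximation.
#' @return List: `statistic` (U for x), `p_value`, `method`, `n` (c(|x|,|y|)),
#'   `exact` flag.
#' @export
mannWhitneyU <- function(x, y, exactLimit = 12L) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= exactLimit) && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "Mann-Whitney U (exact)"
                else "Mann-Whitney U (normal approximation)",
       n = c(length(x), length(y)), exact = exact)
}

.check_groups <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 values")
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(v) == 0) stop("degenerate input: zero overall variance")
  data.frame(value = v, group = g)
}

#' One-way ANOVA
#'
#' F = MS_between / MS_within with the p-value from the F distribution.
#'
#' @param groups List of numeric vectors (>= 2 groups of >= 2 values each).
#' @return List: `statistic` (F), `p_value`, `df`, `method`, `n`.
#' @export
oneWayAnova <- function(groups) {
  d <- .check_groups(groups)
  fit <- stats::aov(value ~ group, data = d)
  s <- summary(fit)[[1]]
  list(statistic = s[["F value"]][1], p_value = s[["Pr(>F)"]][1],
       df = c(s[["Df"]][1], s[["Df"]][2]), method = "one-way ANOVA",
       n = lengths(groups))
}

#' Tukey's honestly-significant-difference post hoc test
#'
#' Studentized-range adjusted p-values for all pairwise group comparisons
#' after a one-way ANOVA; adjusted p-values are never smaller than the
#' corresponding unadjusted pairwise p-values.
#'
#' @param groups Named (or unnamed) list of numeric vectors.
#' @return data.frame: `comparison`, `diff`, `p_adj`.
#' @export
tukeyHsd <- function(groups) {
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  d <- .check_groups(groups)
  levels(d$group) <- names(groups)
  tk <- stats::TukeyHSD(stats::aov(value ~ group, data = d))$group
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             p_adj = tk[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail (accumulative) hypergeometric P(X >= k) for drawing `k` term
#' genes in a list of size `n` from a universe of `N` genes of which `K`
#' belong to the term, with the enrichment factor (k/n)/(K/N).
#'
#' @param geneList Character vector (the query list; must lie in `universe`).
#' @param termGenes Character vector (the term's genes; intersected with the
#'   universe).
#' @param universe Character vector of all background genes.
#' @return List: `k`, `n`, `K`, `N`, `p_value`, `enrichment_factor`, and the
#'   overlapping `genes`.
#' @export
hypergeometricEnrichment <- function(geneList, termGenes, universe) {
  universe <- unique(universe)
  geneList <- unique(geneList)
  if (!all(geneList %in% universe))
    stop("gene list contains genes outside the universe")
  termGenes <- unique(intersect(termGenes, universe))
  k <- length(intersect(geneList, termGenes))
  n <- length(geneList); K <- length(termGenes); N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  factor <- if (n == 0 || K == 0) 0 else (k / n) / (K / N)
  list(k = k, n = n, K = K, N = N, p_value = p, enrichment_factor = factor,
       genes = intersect(geneList, termGenes))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; input order is preserved.
#'
#' @param pvalues Numeric p-values between 0 and 1.
#' @return q-values in the original order.
#' @export
bhFdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie between 0 and 1")
  stats::p.adjust(pvalues, method = "BH")
}

#' Enrichment of a gene list against a GMT collection
#'
#' Runs [hypergeometricEnrichment] per term and appends BH q-values.
#'
#' @param geneList Query gene ids.
#' @param sets Named list of term gene vectors (see [readGmt]).
#' @param universe Background gene ids.
#' @return data.frame: `term`, `k`, `n`, `K`, `N`, `p_value`,
#'   `enrichment_factor`, `q_value`, plus a hidden `genes` list column of
#'   overlap members.
#' @export
enrichGeneSets <- function(geneList, sets, universe) {
  recs <- lapply(sets, hypergeometricEnrichment, geneList = geneList,
                 universe = universe)
  df <- data.frame(term = names(sets),
                   k = vapply(recs, `[[`, 0L, "k"),
                   n = vapply(recs, `[[`, 0L, "n"),
                   K = vapply(recs, `[[`, 0L, "K"),
                   N = vapply(recs, `[[`, 0L, "N"),
                   p_value = vapply(recs, `[[`, 0, "p_value"),
                   enrichment_factor = vapply(recs, `[[`, 0,
                                              "enrichment_factor"),
                   row.names = NULL, stringsAsFactors = FALSE)
  df$q_value <- bhFdr(df$p_value)
  df$genes <- I(lapply(recs, `[[`, "genes"))
  df
}

#' Cohen's kappa between two gene sets
#'
#' Kappa on the 2x2 joint membership table of two binary membership vectors
#' over a common gene background.
#'
#' @param setA,setB Character vectors of gene ids.
#' @param background Character vector over which membership is evaluated.
#' @return Kappa between -1 and 1.
#' @export
cohenKappa <- function(setA, setB, background) {
  a <- background %in% setA
  b <- background %in% setB
  n <- length(background)
  po <- mean(a == b)
  pe <- (mean(a) * mean(b)) + (mean(!a) * mean(!b))
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Filter enriched terms and cluster them by gene-membership similarity
#'
#' Keeps terms passing the standard enrichment filters (p < `pMax`, overlap
#' count >= `minCount`, enrichment factor > `minFactor`), computes pairwise
#' Cohen's kappa on binary gene-membership vectors over the union of the
#' surviving terms' overlap genes, clusters by average-linkage hierarchical
#' clustering on 1 - kappa, and cuts so that terms joined at similarity >
#' `kappaThreshold` share a cluster. Each cluster is represented by its most
#' significant (smallest-p) term.
#'
#' @param records Output of [enrichGeneSets] (needs the `genes` column).
#' @param kappaThreshold Similarity cut (clusters join above this kappa).
#' @param pMax,minCount,minFactor Filter thresholds.
#' @return data.frame of surviving terms with `cluster` id and
#'   `representative` term; zero rows (with a message) if nothing survives.
#' @export
filterAndClusterTerms <- function(records, kappaThreshold = 0.3, pMax = 0.01,
                                  minCount = 3L, minFactor = 1.5) {
  keep <- records$p_value < pMax & records$k >= minCount &
    records$enrichment_factor > minFactor
  surv <- records[keep, , drop = FALSE]
  if (nrow(surv) == 0L) {
    message("no terms survive the enrichment filters")
    surv$cluster <- integer(0)
    surv$representative <- character(0)
    return(surv)
  }
  if (nrow(surv) == 1L) {
    surv$cluster <- 1L
    surv$representative <- surv$term
    return(surv)
  }
  bg <- unique(unlist(surv$genes))
  m <- nrow(surv)
  kap <- matrix(1, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    kap[i, j] <- kap[j, i] <- cohenKappa(surv$genes[[i]], surv$genes[[j]], bg)
  }
  hc <- stats::hclust(stats::as.dist(1 - kap), method = "average")
  cl <- stats::cutree(hc, h = 1 - kappaThreshold)
  surv$cluster <- as.integer(cl)
  rep_of <- vapply(split(seq_len(m), cl), function(idx)
    surv$term[idx[which.min(surv$p_value[idx])]], "")
  surv$representative <- rep_of[as.character(cl)]
  rownames(surv) <- NULL
  surv
}
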