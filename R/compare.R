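# Meta-analyses over enrichment runs: the outcome-permutation false
# discovery rate audit, and the partition of significant pathways between
# the survival-based and fold-change-based analyses.

#' Outcome-permutation FDR audit
#'
#' Estimates how often each pathway is called significant when the
#' expression-outcome association is destroyed: in each of B replicates the
#' per-sample (time, status) pairs are shuffled jointly across samples
#' (jointly, because shuffling time and status independently would create
#' censoring structure no cohort can produce; the survival marginal is
#' preserved exactly), the full survival enrichment pipeline is rerun, and
#' a pathway's estimated FDR is the proportion of replicates in which its
#' adjusted p-value fell below \code{alpha}.
#'
#' The counts, filtering and normalization do not depend on the outcome, so
#' they are computed once and shared across replicates; each replicate
#' refits the per-gene Cox models and the permutation null.
#'
#' @param counts gene x sample count matrix.
#' @param survival data.frame with sample/time/status ([readSurvival()]).
#' @param collection named list of gene sets.
#' @param B number of outcome permutations (fewer than 10 warns: the
#'   per-pathway proportions are then too unstable to read).
#' @param alpha significance level audited.
#' @param seed integer seed driving both the shuffles and the enrichment
#'   permutations.
#' @param minMean low-expression filter threshold.
#' @param nperm enrichment permutation count per replicate (fixed, not
#'   adaptive: resolving p-values far below alpha is wasted work here).
#' @param minSize,maxSize pathway size bounds.
#' @param ties Cox tie correction.
#' @return list: \code{perPathway} (named FDR estimates), \code{average},
#'   \code{B}, \code{alpha}, \code{nTested}.
#' @export
permutationFdrAudit <- function(counts, survival, collection, B = 100,
                                alpha = 0.15, seed = NULL, minMean = 0.1,
                                nperm = 1000, minSize = 3, maxSize = 500,
                                ties = "efron") {
    if (B < 10) warning("B < 10 permutations gives unstable FDR estimates")
    se <- SurvivalExperiment(counts, survival)
    se <- filterLowExpression(se, minMean = minMean, verbose = FALSE)
    nm <- logcpmVoom(se)
    time <- survTime(se)
    status <- survStatus(se)
    n <- ncol(se)
    sigCount <- integer(0)
    testCount <- integer(0)
    for (b in seq_len(B)) {
        if (!is.null(seed)) set.seed(.deriveSeed(seed, b, 1))
        perm <- sample.int(n)
        rl <- rankByLhr(nm$logcpm, time[perm], status[perm], ties = ties,
                        verbose = FALSE)
        res <- runEnrichment(rl, collection, minSize = minSize,
                             maxSize = maxSize, nperm = nperm,
                             npermMax = nperm,
                             seed = .deriveSeed(seed, b, 10),
                             alpha = alpha)
        tab <- enrichTable(res)
        hit <- tab$pathway[tab$padj < alpha]
        for (p in tab$pathway) {
            if (is.na(testCount[p])) { testCount[p] <- 0L; sigCount[p] <- 0L }
            testCount[p] <- testCount[p] + 1L
        }
        for (p in hit) sigCount[p] <- sigCount[p] + 1L
    }
    fdr <- sigCount / B  # untested replicates count as not significant
    list(perPathway = fdr, average = mean(fdr), B = B, alpha = alpha,
         nTested = testCount)
}

#' Partition pathways by significance in two enrichment runs
#'
#' Venn-style counts over the pathways tested in both analyses: significant
#' in both, in only one, or in neither, at a common \code{alpha}.
#'
#' @param resA,resB [EnrichmentResults-class] objects (e.g. survival-based
#'   vs fold-change-based runs).
#' @param alpha significance level applied to both.
#' @return list: \code{both}, \code{onlyA}, \code{onlyB}, \code{neither},
#'   \code{total} (shared pathways), and the pathway id sets
#'   \code{pathways} (a list with the same four names).
#' @export
compareSignificant <- function(resA, resB, alpha = 0.15) {
    ta <- enrichTable(resA)
    tb <- enrichTable(resB)
    shared <- intersect(ta$pathway, tb$pathway)
    if (!length(shared)) stop("the two result tables share no pathway")
    dropped <- (nrow(ta) - length(shared)) + (nrow(tb) - length(shared))
    if (dropped > 0)
        message("compareSignificant: ", dropped,
                " pathway row(s) outside the shared universe ignored")
    sa <- shared %in% ta$pathway[ta$padj < alpha]
    sb <- shared %in% tb$pathway[tb$padj < alpha]
    list(both = sum(sa & sb), onlyA = sum(sa & !sb), onlyB = sum(!sa & sb),
         neither = sum(!sa & !sb), total = length(shared),
         pathways = list(both = shared[sa & sb], onlyA = shared[sa & !sb],
                         onlyB = shared[!sa & sb],
                         neither = shared[!sa & !sb]))
}
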