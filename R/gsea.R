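# The enrichment engine: weighted Kolmogorov-Smirnov-like running-sum
# enrichment score, gene-sampling permutation null, normalized enrichment
# score, permutation p-values with adaptive precision, BH adjustment and
# leading-edge extraction.
#
# The null model samples gene sets of the observed size uniformly from the
# ranked universe (the preranked null): the pipeline is preranked by
# construction, so phenotype permutation does not apply here (the separate
# outcome-permutation audit covers that angle).

.rankedStats <- function(ranked) {
    if (is(ranked, "CoxRankedList")) return(rankStats(ranked))
    stopifnot(is.numeric(ranked), !is.null(names(ranked)))
    ranked
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list top to bottom; a gene-set hit advances the sum by
#' its weight |stat|^exponent (normalized so the hit increments total 1), a
#' miss retreats it by 1/(N - Nh). Both cumulative distributions end at 1,
#' so the walk ends at 0. The enrichment score is the walk's extremum of
#' maximal absolute value, in [-1, 1]; an exact tie between the positive
#' and negative extremum resolves to the positive one. The leading edge is
#' the hits at or before the positive peak (ES > 0), or at or after the
#' negative trough (ES < 0).
#'
#' @param ranked a [CoxRankedList-class] or named numeric vector sorted
#'   decreasing.
#' @param geneSet character vector of member gene ids.
#' @param exponent weighting exponent (1 = classic weighted statistic; 0
#'   would weight all hits equally).
#' @return list: \code{es}, \code{runningSum} (length-N numeric),
#'   \code{peakIndex}, \code{leadingEdge}, \code{hitIndices}, \code{size}.
#' @examples
#' stats <- c(g1 = 3, g2 = 2, g3 = 1)
#' enrichmentScore(stats, "g1")$runningSum  # 1, 0.5, 0
#' @export
enrichmentScore <- function(ranked, geneSet, exponent = 1) {
    stats <- .rankedStats(ranked)
    N <- length(stats)
    hits <- which(names(stats) %in% geneSet)
    nh <- length(hits)
    if (nh == 0L) stop("gene set has no member in the ranked universe")
    if (nh == N) stop("gene set covers the whole ranked universe; the ",
                      "miss increment 1/(N - Nh) is undefined")
    w <- abs(stats)^exponent
    hw <- w[hits]
    denom <- sum(hw)
    if (denom == 0) { hw[] <- 1; denom <- nh }  # all-zero hit stats: equal weights
    step <- rep.int(-1 / (N - nh), N)
    step[hits] <- hw / denom
    running <- cumsum(step)
    top <- max(running)
    bottom <- min(running)
    # ties between the positive and negative extremum resolve positive;
    # the 1e-12 slack keeps exact mathematical ties from flipping on
    # floating-point rounding
    if (top + bottom >= -1e-12) {
        es <- top
        peak <- which.max(running)
        le <- hits[hits <= peak]
    } else {
        es <- bottom
        peak <- which.min(running)
        le <- hits[hits >= peak]
    }
    list(es = es, runningSum = unname(running), peakIndex = peak,
         leadingEdge = names(stats)[le], hitIndices = unname(hits),
         size = nh)
}

# O(k) enrichment score from sorted hit positions only: between hits the
# walk decays linearly, so its extrema occur just after or just before a
# hit. Used by the permutation sampler.
.esFromHits <- function(hitIdx, w, missInc) {
    hw <- w[hitIdx]
    denom <- sum(hw)
    if (denom == 0) { hw[] <- 1; denom <- length(hw) }
    after <- cumsum(hw) / denom - (hitIdx - seq_along(hitIdx)) * missInc
    before <- after - hw / denom
    top <- max(after)
    bottom <- min(before)
    if (top + bottom >= -1e-12) top else bottom
}

#' Sample the gene-permutation null distribution of the enrichment score
#'
#' Draws \code{nperm} gene sets of a given size uniformly without
#' replacement from the ranked universe and returns their enrichment
#' scores. One null sample is shared across all same-size pathways within
#' a run.
#'
#' @inheritParams enrichmentScore
#' @param setSize gene set size (0 < setSize < universe size).
#' @param nperm number of permutations (a value below 100 triggers a
#'   warning: the resulting p-values are too coarse to be useful).
#' @param seed optional integer seed for reproducibility.
#' @return numeric vector of \code{nperm} null enrichment scores.
#' @export
sampleNullEs <- function(ranked, setSize, nperm, seed = NULL, exponent = 1) {
    stats <- .rankedStats(ranked)
    N <- length(stats)
    if (setSize <= 0L || setSize >= N)
        stop("setSize must satisfy 0 < setSize < ", N)
    if (nperm < 100)
        warning("nperm < 100 gives very coarse permutation p-values")
    if (!is.null(seed)) set.seed(seed)
    w <- abs(unname(stats))^exponent
    missInc <- 1 / (N - setSize)
    vapply(seq_len(nperm), function(i)
        .esFromHits(sort.int(sample.int(N, setSize)), w, missInc),
        numeric(1))
}

#' Normalized enrichment score and permutation p-value
#'
#' NES divides the observed ES by the mean |ES| of same-sign null draws;
#' the p-value is the add-one-corrected proportion of same-sign null draws
#' at least as extreme, so it is always in (0, 1]. If the null sample
#' contains no draw of the observed sign, a one-sided fallback against the
#' full |null| distribution is used and flagged.
#'
#' @param es observed enrichment score.
#' @param nullSample numeric vector of null enrichment scores (same set
#'   size).
#' @return list: \code{nes}, \code{pval}, \code{nSame} (null draws used),
#'   \code{flagged} (fallback indicator).
#' @export
nesAndPvalue <- function(es, nullSample) {
    sgn <- if (es >= 0) 1 else -1
    same <- nullSample[sign(nullSample) == sgn]
    flagged <- FALSE
    if (!length(same)) {
        same <- abs(nullSample)
        flagged <- TRUE
    }
    m <- mean(abs(same))
    nes <- if (m > 0) es / m else 0
    pval <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    list(nes = nes, pval = pval, nSame = length(same), flagged = flagged)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wrapper over \code{stats::p.adjust}).
#'
#' @param pvals numeric p-values in (0, 1].
#' @return adjusted p-values, capped at 1.
#' @export
bhAdjust <- function(pvals) stats::p.adjust(pvals, method = "BH")

.deriveSeed <- function(seed, size, level) {
    if (is.null(seed)) return(NULL)
    as.integer((as.numeric(seed) + 100003 * size +
                977 * round(log10(level))) %% 2147483629L + 1)
}

#' Run a full gene set enrichment analysis on a ranked list
#'
#' For every pathway intersecting the ranked universe within the size
#' bounds: enrichment score, gene-sampling permutation p-value, NES,
#' leading edge. Permutation precision is adaptive: every pathway starts at
#' \code{nperm} draws, and any pathway whose p-value falls below
#' 10/nperm is re-evaluated at tenfold more draws, up to \code{npermMax},
#' so small p-values are resolved without spending large permutation
#' budgets on null pathways. Null draws are shared across same-size
#' pathways. BH adjustment is applied across all tested pathways.
#'
#' The \code{log2err} column is the Monte-Carlo standard error of
#' log2(pval) implied by the permutation count
#' (sqrt((1 - p) / (p n)) / ln 2); it is not comparable to the split-sample
#' error estimate of multilevel implementations.
#'
#' @inheritParams enrichmentScore
#' @param collection named list of gene sets ([readGmt()] output).
#' @param minSize,maxSize pathway size bounds after intersection with the
#'   universe (defaults 3 and 500).
#' @param nperm starting permutation count per pathway.
#' @param npermMax adaptive ceiling on the permutation count.
#' @param seed integer seed making the whole table reproducible.
#' @param alpha significance level recorded in the result (default 0.15,
#'   the conventional threshold for enrichment screens of this kind).
#' @return An [EnrichmentResults-class]; rows ordered by pval.
#' @examples
#' sim <- simulateSurvivalDataset(n_samples = 80, n_genes = 120,
#'                                n_pathways = 5, seed = 7)
#' nm <- logcpmVoom(sim$counts)
#' rl <- rankByLhr(nm, sim$survival$time, sim$survival$status)
#' res <- runEnrichment(rl, sim$pathways, seed = 7)
#' head(enrichTable(res))
#' @export
runEnrichment <- function(ranked, collection, minSize = 3, maxSize = 500,
                          nperm = 1000, npermMax = 1e6, seed = NULL,
                          alpha = 0.15, exponent = 1) {
    stats <- .rankedStats(ranked)
    N <- length(stats)
    universe <- names(stats)
    members <- lapply(collection, function(g) intersect(g, universe))
    sizes <- lengths(members)
    keep <- sizes >= minSize & sizes <= maxSize & sizes < N
    if (!any(keep)) {
        stop("no pathway within size bounds [", minSize, ", ", maxSize,
             "] after intersection with the ", N, "-gene universe; ",
             "observed sizes: ",
             paste(utils::capture.output(print(summary(sizes))),
                   collapse = " "))
    }
    members <- members[keep]
    sizes <- sizes[keep]
    P <- length(members)
    esr <- lapply(members, function(g) enrichmentScore(stats, g, exponent))
    es <- vapply(esr, `[[`, numeric(1), "es")
    pval <- nes <- log2err <- rep(NA_real_, P)
    level <- rep(nperm, P)
    done <- rep(FALSE, P)
    while (any(!done)) {
        np <- min(level[!done])
        idx <- which(!done & level == np)
        nulls <- lapply(unique(sizes[idx]), function(k)
            sampleNullEs(stats, k, np, seed = .deriveSeed(seed, k, np),
                         exponent = exponent))
        names(nulls) <- as.character(unique(sizes[idx]))
        for (i in idx) {
            r <- nesAndPvalue(es[i], nulls[[as.character(sizes[i])]])
            pval[i] <- r$pval
            nes[i] <- r$nes
            log2err[i] <- sqrt((1 - r$pval) / (r$pval * r$nSame)) / log(2)
        }
        escalate <- !done & level == np & pval < 10 / np & np < npermMax
        level[escalate] <- pmin(np * 10, npermMax)
        done[idx] <- !escalate[idx]
    }
    tab <- data.frame(pathway = names(members), pval = pval,
                      padj = bhAdjust(pval), log2err = log2err, ES = es,
                      NES = nes, size = as.integer(sizes),
                      stringsAsFactors = FALSE)
    tab$leadingEdge <- lapply(esr, `[[`, "leadingEdge")
    tab <- tab[order(tab$pval, -abs(tab$NES), tab$pathway), ]
    rownames(tab) <- NULL
    mode <- if (is(ranked, "CoxRankedList")) rankingMode(ranked) else "external"
    new("EnrichmentResults", table = tab, alpha = alpha,
        params = list(minSize = minSize, maxSize = maxSize, nperm = nperm,
                      npermMax = npermMax, seed = seed, exponent = exponent,
                      mode = mode, nperm_final = level))
}
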