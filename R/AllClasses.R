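#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' SurvivalExperiment: expression counts with censored survival metadata
#'
#' Container coupling a gene x sample count matrix with per-sample
#' time-to-event data. Extends
#' \link[SummarizedExperiment]{SummarizedExperiment}; the survival outcome
#' lives in \code{colData} as columns \code{time} (positive, one unit
#' throughout, e.g. days) and \code{status} (1 = event observed, 0 =
#' censored). Any further \code{colData} columns are available as Cox
#' covariates.
#'
#' @slot .. see \link[SummarizedExperiment]{SummarizedExperiment}; no extra
#'   slots are added, only validity constraints.
#' @seealso [SurvivalExperiment()] the constructor, [survTime()],
#'   [survStatus()]
#' @export
setClass("SurvivalExperiment", contains = "SummarizedExperiment")

setValidity("SurvivalExperiment", function(object) {
    msg <- character()
    cd <- colData(object)
    if (!all(c("time", "status") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'time' and 'status' columns")
    else {
        tm <- cd$time
        st <- cd$status
        if (!is.numeric(tm) || any(!is.finite(tm)) || any(tm <= 0))
            msg <- c(msg, "'time' must be finite and > 0 for every sample")
        if (!all(st %in% c(0, 1)))
            msg <- c(msg, "'status' must be 0 (censored) or 1 (event)")
    }
    if (!"counts" %in% names(assays(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- assay(object, "counts")
        if (any(!is.finite(cnt)) || any(cnt < 0))
            msg <- c(msg, "counts must be finite and non-negative")
    }
    if (ncol(object) < 2L)
        msg <- c(msg, "at least 2 samples are required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene identifiers")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample identifiers")
    if (length(msg)) msg else TRUE
})

#' Construct a SurvivalExperiment
#'
#' Intersects the samples of a count matrix with a survival table and builds
#' a validated [SurvivalExperiment-class]. Sample order follows the count
#' matrix restricted to the intersection, so shuffled inputs yield the same
#' object.
#'
#' @param counts gene x sample matrix of non-negative counts with unique
#'   dimnames (as returned by [readCounts()]).
#' @param survival data.frame with columns \code{sample}, \code{time},
#'   \code{status} and optional numeric covariates (as returned by
#'   [readSurvival()]).
#' @return A [SurvivalExperiment-class].
#' @examples
#' sim <- simulateSurvivalDataset(n_samples = 20, n_genes = 30, seed = 1)
#' se <- SurvivalExperiment(sim$counts, sim$survival)
#' se
#' @export
SurvivalExperiment <- function(counts, survival) {
    stopifnot(is.matrix(counts), is.data.frame(survival))
    if (!"sample" %in% colnames(survival))
        stop("'survival' must have a 'sample' column")
    shared <- intersect(colnames(counts), survival$sample)
    if (length(shared) < 2L)
        stop("fewer than 2 samples shared between counts (",
             ncol(counts), ") and survival (", nrow(survival), ")")
    dropped <- (ncol(counts) - length(shared)) +
        (nrow(survival) - length(shared))
    if (dropped > 0L)
        message("SurvivalExperiment: dropped ", dropped,
                " unmatched sample record(s); ", length(shared), " retained")
    counts <- counts[, shared, drop = FALSE]
    survival <- survival[match(shared, survival$sample), , drop = FALSE]
    cd <- DataFrame(survival[, setdiff(colnames(survival), "sample"),
                             drop = FALSE],
                    row.names = shared)
    new("SurvivalExperiment",
        SummarizedExperiment(assays = list(counts = counts), colData = cd))
}

#' CoxRankedList: genes ordered by a ranking statistic
#'
#' Genes sorted in decreasing order of a per-gene statistic: Cox log hazard
#' ratios in survival mode ("lhr") or negative-binomial log2 fold changes in
#' case-control mode ("lfc"). Ties are broken lexicographically by gene id,
#' so the ranking is fully reproducible. Genes whose fits did not converge
#' (or were non-informative) are excluded and recorded.
#'
#' @slot stats named numeric vector, sorted decreasing, one finite value per
#'   gene.
#' @slot mode "lhr" or "lfc".
#' @slot excluded character vector of gene ids dropped from the ranking.
#' @slot details data.frame of per-gene fit statistics (beta/log2fc, se, z,
#'   p, ...) for the retained genes, in ranking order.
#' @export
setClass("CoxRankedList",
         representation(stats = "numeric", mode = "character",
                        excluded = "character", details = "data.frame"))

setValidity("CoxRankedList", function(object) {
    msg <- character()
    s <- object@stats
    if (is.null(names(s)) || anyDuplicated(names(s)))
        msg <- c(msg, "stats must be uniquely named by gene id")
    if (any(!is.finite(s)))
        msg <- c(msg, "statistics must be finite")
    if (is.unsorted(rev(s)))
        msg <- c(msg, "stats must be sorted in decreasing order")
    ties <- split(names(s), s)
    if (any(vapply(ties, is.unsorted, logical(1))))
        msg <- c(msg, "tied statistics must be in lexicographic gene order")
    if (!object@mode %in% c("lhr", "lfc", "external"))
        msg <- c(msg, "mode must be 'lhr', 'lfc' or 'external'")
    if (length(msg)) msg else TRUE
})

#' Build a CoxRankedList from a named statistic vector
#'
#' Sorts decreasing with lexicographic tie-breaking and validates.
#'
#' @param stats named numeric vector (gene id -> ranking statistic).
#' @param mode ranking statistic kind: "lhr", "lfc" or "external".
#' @param excluded gene ids dropped before ranking (non-converged fits).
#' @param details optional per-gene fit table (re-ordered to match ranking).
#' @return A [CoxRankedList-class].
#' @export
CoxRankedList <- function(stats, mode = "external",
                          excluded = character(), details = NULL) {
    keep <- is.finite(stats)
    stats <- stats[keep]
    ord <- order(-stats, names(stats), method = "radix")
    stats <- stats[ord]
    if (is.null(details))
        details <- data.frame(gene = names(stats), stat = unname(stats))
    else
        details <- details[match(names(stats), details$gene), , drop = FALSE]
    rownames(details) <- NULL
    new("CoxRankedList", stats = stats, mode = mode,
        excluded = as.character(excluded), details = details)
}

#' EnrichmentResults: per-pathway enrichment statistics
#'
#' One row per tested pathway with the standard output schema: permutation
#' p-value, BH-adjusted p-value, Monte-Carlo log2 error of the p-value
#' estimate, enrichment score, normalized enrichment score, pathway size in
#' the ranked universe, and the leading-edge genes.
#'
#' @slot table data.frame with columns pathway, pval, padj, log2err, ES,
#'   NES, size, leadingEdge (list column of character vectors).
#' @slot alpha significance level used for the significance flag.
#' @slot params list recording the run (nperm policy, seed, exponent, size
#'   bounds, ranking mode).
#' @export
setClass("EnrichmentResults",
         representation(table = "data.frame", alpha = "numeric",
                        params = "list"))

setValidity("EnrichmentResults", function(object) {
    msg <- character()
    need <- c("pathway", "pval", "padj", "log2err", "ES", "NES", "size",
              "leadingEdge")
    tab <- object@table
    if (!all(need %in% colnames(tab)))
        msg <- c(msg, paste("missing columns:",
                            paste(setdiff(need, colnames(tab)), collapse = ", ")))
    else if (nrow(tab)) {
        if (any(tab$pval <= 0 | tab$pval > 1)) msg <- c(msg, "pval outside (0,1]")
        if (any(tab$padj < tab$pval - 1e-12)) msg <- c(msg, "padj < pval")
        if (any(sign(tab$NES) != sign(tab$ES)))
            msg <- c(msg, "sign(NES) != sign(ES)")
        if (any(abs(tab$ES) > 1 + 1e-9)) msg <- c(msg, "|ES| > 1")
    }
    if (length(msg)) msg else TRUE
})
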