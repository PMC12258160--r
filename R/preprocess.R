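# Count preprocessing: mean-count filtering, voom-style log2-CPM
# normalization (for the Cox/survival path), median-of-ratios size factors
# (for the negative-binomial fold-change path).

#' Filter genes by mean count per sample
#'
#' Removes genes averaging fewer than \code{minMean} reads per sample
#' (default 0.1, i.e. less than 1 read per 10 samples on average). The rule
#' is a strict "less than": a gene whose mean is exactly \code{minMean} is
#' kept. Idempotent, and monotone in \code{minMean}.
#'
#' @param counts gene x sample count matrix or [SurvivalExperiment-class].
#' @param minMean minimum mean count per sample (reads/sample).
#' @param verbose message the number of removed genes.
#' @return object of the same class with low-expression genes removed.
#' @examples
#' m <- rbind(lo = c(0, 1, 0, 0), hi = c(9, 7, 12, 8))
#' colnames(m) <- paste0("s", 1:4)
#' rownames(filterLowExpression(m, minMean = 0.5))
#' @export
setGeneric("filterLowExpression",
           function(counts, minMean = 0.1, verbose = TRUE)
               standardGeneric("filterLowExpression"))

#' @rdname filterLowExpression
#' @export
setMethod("filterLowExpression", "matrix",
          function(counts, minMean = 0.1, verbose = TRUE) {
    stopifnot(minMean >= 0, all(counts >= 0))
    keep <- rowMeans(counts) >= minMean
    if (!any(keep))
        stop("filterLowExpression: no gene passes minMean = ", minMean)
    if (verbose)
        message(sprintf("filterLowExpression: removed %d/%d genes below %g %s",
                        sum(!keep), length(keep), minMean,
                        "mean reads/sample"))
    counts[keep, , drop = FALSE]
})

#' @rdname filterLowExpression
#' @export
setMethod("filterLowExpression", "SurvivalExperiment",
          function(counts, minMean = 0.1, verbose = TRUE) {
    keep <- rownames(filterLowExpression(assay(counts, "counts"),
                                         minMean = minMean,
                                         verbose = verbose))
    counts[keep, ]
})

#' Voom-style log2-CPM normalization
#'
#' Computes log2-CPM values \code{log2((count + 0.5) / (libsize + 1) * 1e6)}
#' and per-observation precision weights from a lowess mean-variance trend,
#' delegating to \code{limma::voom} with an intercept-only design. The
#' weights are stored for sensitivity analysis, but the Cox ranking stage
#' consumes only the log-CPM values by default (an unweighted partial
#' likelihood is the defensible default; nothing in the method requires
#' precision-weighted Cox fits).
#'
#' @param counts gene x sample count matrix or [SurvivalExperiment-class].
#' @return list with elements \code{logcpm} (gene x sample matrix),
#'   \code{weights} (same shape, inverse predicted variances), and
#'   \code{recipe} (normalization record).
#' @examples
#' sim <- simulateSurvivalDataset(n_samples = 10, n_genes = 25, seed = 1)
#' nm <- logcpmVoom(sim$counts)
#' nm$logcpm[1:3, 1:3]
#' @export
setGeneric("logcpmVoom", function(counts) standardGeneric("logcpmVoom"))

#' @rdname logcpmVoom
#' @export
setMethod("logcpmVoom", "matrix", function(counts) {
    stopifnot(ncol(counts) >= 2, all(counts >= 0))
    lib <- colSums(counts)
    if (any(lib == 0))
        stop("sample(s) with zero library size: ",
             paste(colnames(counts)[lib == 0], collapse = ", "))
    v <- limma::voom(counts, design = NULL)
    list(logcpm = v$E, weights = v$weights,
         recipe = list(method = "voom log2-CPM",
                       offset = "count + 0.5, libsize + 1",
                       lib.size = lib))
})

#' @rdname logcpmVoom
#' @export
setMethod("logcpmVoom", "SurvivalExperiment",
          function(counts) logcpmVoom(assay(counts, "counts")))

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants for negative binomial count models: each
#' sample's factor is the median, over genes positive in every sample, of
#' the ratio of its count to the gene's geometric mean across samples.
#'
#' @param counts gene x sample count matrix.
#' @return named positive numeric vector, one factor per sample.
#' @examples
#' m <- rbind(a = c(10, 20), b = c(5, 10), c = c(8, 16))
#' colnames(m) <- c("s1", "s2")
#' medianRatioSizeFactors(m)  # ratio exactly 2
#' @export
medianRatioSizeFactors <- function(counts) {
    stopifnot(is.matrix(counts), all(counts >= 0))
    allPos <- rowSums(counts > 0) == ncol(counts)
    if (!any(allPos))
        stop("no gene has nonzero counts in every sample; ",
             "apply stronger low-expression filtering first")
    lm <- log(counts[allPos, , drop = FALSE])
    geo <- rowMeans(lm)
    sf <- apply(lm, 2L, function(col) exp(stats::median(col - geo)))
    stats::setNames(sf, colnames(counts))
}
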