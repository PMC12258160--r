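#' Survival accessors
#'
#' @param x a [SurvivalExperiment-class]
#' @return numeric vector of follow-up times / 0-1 event indicators /
#'   integer event count.
#' @export
setGeneric("survTime", function(x) standardGeneric("survTime"))

#' @rdname survTime
#' @export
setGeneric("survStatus", function(x) standardGeneric("survStatus"))

#' @rdname survTime
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname survTime
#' @export
setMethod("survTime", "SurvivalExperiment", function(x) colData(x)$time)

#' @rdname survTime
#' @export
setMethod("survStatus", "SurvivalExperiment", function(x) colData(x)$status)

#' @rdname survTime
#' @export
setMethod("nEvents", "SurvivalExperiment",
          function(x) sum(colData(x)$status == 1))

setMethod("show", "SurvivalExperiment", function(object) {
    callNextMethod()
    cat(sprintf("survival: %d events / %d samples (%.0f%% censored)\n",
                nEvents(object), ncol(object),
                100 * mean(survStatus(object) == 0)))
})

#' Ranked list accessors
#'
#' @param x a [CoxRankedList-class]
#' @return gene ids in rank order / named statistic vector / mode string /
#'   excluded gene ids.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname geneIds
#' @export
setGeneric("rankStats", function(x) standardGeneric("rankStats"))

#' @rdname geneIds
#' @export
setGeneric("rankingMode", function(x) standardGeneric("rankingMode"))

#' @rdname geneIds
#' @export
setGeneric("excludedGenes", function(x) standardGeneric("excludedGenes"))

#' @rdname geneIds
#' @export
setMethod("geneIds", "CoxRankedList", function(x) names(x@stats))

#' @rdname geneIds
#' @export
setMethod("rankStats", "CoxRankedList", function(x) x@stats)

#' @rdname geneIds
#' @export
setMethod("rankingMode", "CoxRankedList", function(x) x@mode)

#' @rdname geneIds
#' @export
setMethod("excludedGenes", "CoxRankedList", function(x) x@excluded)

setMethod("show", "CoxRankedList", function(object) {
    n <- length(object@stats)
    cat(sprintf("CoxRankedList of %d genes (mode: %s, %d excluded)\n",
                n, object@mode, length(object@excluded)))
    if (n) {
        hd <- utils::head(object@stats, 3)
        tl <- utils::tail(object@stats, 3)
        cat("  top:   ", paste(sprintf("%s=%.3g", names(hd), hd),
                               collapse = ", "), "\n")
        cat("  bottom:", paste(sprintf("%s=%.3g", names(tl), tl),
                               collapse = ", "), "\n")
    }
})

#' @rdname geneIds
#' @param ... unused
#' @export
setMethod("length", "CoxRankedList", function(x) length(x@stats))

#' Enrichment results accessors
#'
#' @param x an [EnrichmentResults-class]
#' @param alpha significance level; defaults to the level stored in the
#'   object (0.15 unless overridden at run time).
#' @return `enrichTable`: the full result data.frame; `significant`: the
#'   subset with padj < alpha.
#' @export
setGeneric("enrichTable", function(x) standardGeneric("enrichTable"))

#' @rdname enrichTable
#' @export
setGeneric("significant", function(x, alpha) standardGeneric("significant"))

#' @rdname enrichTable
#' @export
setMethod("enrichTable", "EnrichmentResults", function(x) x@table)

#' @rdname enrichTable
#' @export
setMethod("significant", "EnrichmentResults", function(x, alpha) {
    if (missing(alpha)) alpha <- x@alpha
    x@table[x@table$padj < alpha, , drop = FALSE]
})

setMethod("show", "EnrichmentResults", function(object) {
    tab <- object@table
    cat(sprintf("EnrichmentResults: %d pathways, %d significant at padj < %g\n",
                nrow(tab), sum(tab$padj < object@alpha), object@alpha))
    if (nrow(tab)) {
        top <- tab[order(tab$padj, -abs(tab$NES)), ][seq_len(min(5, nrow(tab))), ]
        print(data.frame(pathway = substr(top$pathway, 1, 40),
                         pval = signif(top$pval, 3),
                         padj = signif(top$padj, 3),
                         NES = round(top$NES, 2), size = top$size))
    }
})

#' @rdname enrichTable
#' @param row.names,optional,... passed on conventionally, unused.
#' @export
setMethod("as.data.frame", "EnrichmentResults",
          function(x, row.names = NULL, optional = FALSE, ...) x@table)
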