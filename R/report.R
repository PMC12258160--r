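# Reporting helpers: top-k significant pathway tables for each enrichment
# direction, and the data behind per-pathway enrichment plots.

#' Top significant pathways by direction
#'
#' Among pathways with padj < alpha, returns the k strongest with NES > 0
#' (expression associated with mortality, in survival mode) and the k
#' strongest with NES < 0 (associated with survival), each sorted by |NES|
#' decreasing by default, or by adjusted p-value. Fewer than k rows are
#' returned when fewer qualify; no qualifying pathway yields empty tables,
#' not an error.
#'
#' @param results an [EnrichmentResults-class].
#' @param k rows per direction.
#' @param alpha significance level (default: the level stored in
#'   \code{results}).
#' @param orderBy "nes" (|NES| decreasing) or "padj" (increasing).
#' @return list of two data.frames: \code{positive}, \code{negative}.
#' @export
topTables <- function(results, k = 10, alpha = NULL,
                      orderBy = c("nes", "padj")) {
    orderBy <- match.arg(orderBy)
    if (is.null(alpha)) alpha <- results@alpha
    tab <- enrichTable(results)
    sig <- tab[tab$padj < alpha, , drop = FALSE]
    pick <- function(rows) {
        ord <- if (orderBy == "nes") order(-abs(rows$NES), rows$pathway)
               else order(rows$padj, -abs(rows$NES), rows$pathway)
        out <- rows[ord, , drop = FALSE][seq_len(min(k, nrow(rows))), ,
                                         drop = FALSE]
        rownames(out) <- NULL
        out
    }
    list(positive = pick(sig[sig$NES > 0, , drop = FALSE]),
         negative = pick(sig[sig$NES < 0, , drop = FALSE]))
}

#' Data behind a per-pathway enrichment plot
#'
#' Exposes the full running sum, hit tick positions, peak and the
#' underlying ranking statistics, so the classic enrichment figure (walk
#' line, hit rug, statistic panel) can be drawn by [plotEnrichment()] or
#' any external plotting code.
#'
#' @inheritParams enrichmentScore
#' @return list: \code{runningSum}, \code{hitIndices}, \code{es},
#'   \code{peakIndex}, \code{leadingEdge}, \code{stats} (named ranking
#'   statistics in rank order), \code{size}.
#' @export
enrichmentPlotData <- function(ranked, geneSet, exponent = 1) {
    stats <- .rankedStats(ranked)
    esr <- enrichmentScore(stats, geneSet, exponent)
    c(esr[c("runningSum", "hitIndices", "es", "peakIndex", "leadingEdge",
            "size")],
      list(stats = stats))
}

#' Draw a per-pathway enrichment plot
#'
#' Running-sum line with a hit rug underneath; the peak defining the
#' enrichment score is marked.
#'
#' @inheritParams enrichmentScore
#' @param title plot title (e.g. the pathway name).
#' @return a ggplot object.
#' @export
plotEnrichment <- function(ranked, geneSet, exponent = 1, title = NULL) {
    pd <- enrichmentPlotData(ranked, geneSet, exponent)
    df <- data.frame(rank = seq_along(pd$runningSum), es = pd$runningSum)
    rug <- data.frame(rank = pd$hitIndices)
    ymin <- min(0, min(df$es))
    tick <- 0.06 * (max(df$es) - ymin + 1e-9)
    ggplot2::ggplot(df, ggplot2::aes(x = rank, y = es)) +
        ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
        ggplot2::geom_line(colour = "#2c7fb8") +
        ggplot2::geom_segment(data = rug,
                              ggplot2::aes(x = rank, xend = rank,
                                           y = ymin - 2 * tick,
                                           yend = ymin - tick),
                              inherit.aes = FALSE, linewidth = 0.2) +
        ggplot2::geom_vline(xintercept = pd$peakIndex, linetype = 2,
                            colour = "grey40") +
        ggplot2::labs(title = title,
                      subtitle = sprintf("ES = %.3f (%d genes in set)",
                                         pd$es, pd$size),
                      x = "rank in gene list", y = "running enrichment score") +
        ggplot2::theme_minimal()
}
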