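# Independent oracles and tiny fixture builders shared across tests.
# These deliberately avoid the package's own code paths: the partial
# likelihood is written as a direct double loop over risk sets, and the
# enrichment score as the explicit difference of the two cumulative
# distributions, maximized over prefixes.

# Direct partial log-likelihood (Efron/Breslow), double loop over event
# times; no shared code with the package's cumulative-sum implementation.
naiveCoxLoglik <- function(beta, x, time, status, ties = "efron") {
    ll <- 0
    for (ut in unique(time[status == 1])) {
        D <- which(time == ut & status == 1)
        R <- which(time >= ut)
        d <- length(D)
        ll <- ll + beta * sum(x[D])
        for (l in seq_len(d) - 1) {
            frac <- if (ties == "efron") l / d else 0
            ll <- ll - log(sum(exp(beta * x[R])) - frac * sum(exp(beta * x[D])))
        }
    }
    ll
}

# Exhaustive grid maximization of the naive partial likelihood.
gridCoxBeta <- function(x, time, status, ties = "efron", lim = 10,
                        step = 1e-3) {
    grid <- seq(-lim, lim, by = step)
    E <- exp(outer(grid, x))
    ll <- numeric(length(grid))
    for (ut in unique(time[status == 1])) {
        D <- which(time == ut & status == 1)
        R <- which(time >= ut)
        d <- length(D)
        ll <- ll + grid * sum(x[D])
        sR <- rowSums(E[, R, drop = FALSE])
        sD <- rowSums(E[, D, drop = FALSE])
        for (l in seq_len(d) - 1) {
            frac <- if (ties == "efron") l / d else 0
            ll <- ll - log(sR - frac * sD)
        }
    }
    grid[which.max(ll)]
}

# Brute-force enrichment score: P_hit - P_miss over every prefix, extremum
# by absolute value with ties resolved to the positive side.
bruteEs <- function(stats, geneSet, exponent = 1) {
    hit <- names(stats) %in% geneSet
    N <- length(stats)
    nh <- sum(hit)
    w <- abs(stats)^exponent
    phit <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
    pmiss <- cumsum(!hit) / (N - nh)
    dev <- phit - pmiss
    top <- max(dev)
    bottom <- min(dev)
    # same tie rule as the implementation under test: exact ties (to 1e-12)
    # between the two extrema resolve positive
    if (top + bottom >= -1e-12) top else bottom
}

# A small fixed enrichment table wrapped as EnrichmentResults.
makeResults <- function(pathway, pval, nes, size = 10, alpha = 0.15) {
    n <- length(pathway)
    tab <- data.frame(pathway = pathway, pval = pval,
                      padj = p.adjust(pval, "BH"),
                      log2err = rep(NA_real_, n), ES = nes / 4, NES = nes,
                      size = rep_len(size, n), stringsAsFactors = FALSE)
    tab$leadingEdge <- replicate(length(pathway), c("gA", "gB"),
                                 simplify = FALSE)
    new("EnrichmentResults", table = tab, alpha = alpha, params = list())
}

writeTempCsv <- function(df, rowNames = TRUE) {
    f <- tempfile(fileext = ".csv")
    utils::write.csv(df, f, row.names = rowNames, quote = FALSE)
    f
}
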