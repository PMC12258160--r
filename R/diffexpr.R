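# Negative-binomial GLM log2 fold changes between two conditions (e.g.
# tumor vs normal), feeding the standard fold-change-based enrichment mode.
# This is a plain NB Wald GLM on raw counts with median-of-ratios offsets:
# no dispersion shrinkage toward a trend and no fold-change shrinkage, so
# bit-exact parity with heavier differential-expression machinery is not a
# goal -- the fold changes only serve as an enrichment ranking here.

#' Per-gene negative binomial dispersion estimates
#'
#' Method-of-moments start on size-factor-normalized counts pooled within
#' condition (alpha = (s^2 - m) / m^2, condition-wise, pooled by degrees of
#' freedom), refined by a per-gene maximum-likelihood step with the group
#' means profiled at their normalized sample means. Estimates are floored
#' at 1e-8, which degenerate (zero-variance) genes receive directly.
#'
#' @param counts gene x sample count matrix.
#' @param sizeFactors per-sample positive scale factors
#'   ([medianRatioSizeFactors()]); computed if NULL.
#' @param condition per-sample condition labels (two levels).
#' @return named numeric vector of per-gene dispersions (>= 1e-8).
#' @export
estimateDispersion <- function(counts, condition, sizeFactors = NULL) {
    stopifnot(is.matrix(counts), ncol(counts) == length(condition))
    cond <- factor(condition)
    if (nlevels(cond) != 2L) stop("exactly two condition levels required")
    if (min(table(cond)) < 2L) stop("need >= 2 samples per condition")
    if (is.null(sizeFactors)) sizeFactors <- medianRatioSizeFactors(counts)
    floorA <- 1e-8
    y <- sweep(counts, 2L, sizeFactors, "/")
    alpha <- vapply(seq_len(nrow(counts)), function(g) {
        yg <- y[g, ]
        mom <- 0
        wsum <- 0
        for (lv in levels(cond)) {
            v <- yg[cond == lv]
            m <- mean(v)
            if (m > 0 && length(v) > 1L) {
                a <- (stats::var(v) - m) / m^2
                mom <- mom + a * (length(v) - 1L)
                wsum <- wsum + (length(v) - 1L)
            }
        }
        mom <- if (wsum > 0) max(0, mom / wsum) else 0
        mu <- ave(yg, cond)  # normalized group means, per sample
        muObs <- mu * sizeFactors
        if (all(muObs == 0) || stats::var(counts[g, ] - muObs) == 0)
            return(floorA)
        nll <- function(la)
            -sum(stats::dnbinom(counts[g, ], mu = pmax(muObs, 1e-12),
                                size = 1 / exp(la), log = TRUE))
        lo <- log(max(floorA, mom / 20))
        hi <- log(max(50, mom * 20))
        opt <- stats::optimize(nll, interval = c(log(floorA), hi))
        max(floorA, exp(opt$minimum))
    }, numeric(1))
    stats::setNames(alpha, rownames(counts))
}

#' Negative binomial Wald log2 fold changes
#'
#' Fits, per gene, an NB GLM with log link, design intercept + condition
#' (plus an optional pair-indicator block for paired designs), and log
#' size-factor offsets, at fixed per-gene dispersion. The reported log2
#' fold change is the condition coefficient divided by ln 2 (second factor
#' level vs first); the Wald p-value uses the observed information with
#' dispersion fixed at its estimate.
#'
#' A gene with zero counts throughout one condition has no finite MLE; its
#' fold change falls back to a 0.5 pseudo-mean on the normalized scale and
#' the row is flagged.
#'
#' @inheritParams estimateDispersion
#' @param dispersions per-gene NB dispersions ([estimateDispersion()]);
#'   computed if NULL.
#' @param pairs optional per-sample pair identifiers for paired designs.
#' @return data.frame: gene, log2fc, se, wald_p, dispersion, basemean,
#'   flagged.
#' @export
nbWaldLfc <- function(counts, condition, sizeFactors = NULL,
                      dispersions = NULL, pairs = NULL) {
    cond <- factor(condition)
    if (nlevels(cond) != 2L) stop("exactly two condition levels required")
    if (is.null(sizeFactors)) sizeFactors <- medianRatioSizeFactors(counts)
    if (is.null(dispersions))
        dispersions <- estimateDispersion(counts, cond, sizeFactors)
    off <- log(sizeFactors)
    df0 <- data.frame(cond = cond)
    if (!is.null(pairs)) df0$pair <- factor(pairs)
    form <- if (is.null(pairs)) y ~ cond else y ~ cond + pair
    ln2 <- log(2)
    res <- lapply(seq_len(nrow(counts)), function(g) {
        yg <- counts[g, ]
        ynorm <- yg / sizeFactors
        gm <- tapply(ynorm, cond, mean)
        bm <- mean(ynorm)
        if (any(gm == 0)) {
            gmStar <- pmax(gm, 0.5)  # pseudo-mean fallback
            return(data.frame(log2fc = log2(gmStar[[2L]] / gmStar[[1L]]),
                              se = NA_real_, wald_p = NA_real_,
                              dispersion = dispersions[g], basemean = bm,
                              flagged = TRUE))
        }
        dat <- df0
        dat$y <- yg
        theta <- 1 / max(dispersions[g], 1e-8)
        fit <- suppressWarnings(tryCatch(
            stats::glm(form, data = dat,
                       family = MASS::negative.binomial(theta = theta),
                       offset = off),
            error = function(e) NULL))
        if (is.null(fit) || !fit$converged)
            return(data.frame(log2fc = log2(gm[[2L]] / gm[[1L]]),
                              se = NA_real_, wald_p = NA_real_,
                              dispersion = dispersions[g], basemean = bm,
                              flagged = TRUE))
        sm <- stats::coef(summary(fit, dispersion = 1))
        co <- sm[2L, "Estimate"]
        se <- sm[2L, "Std. Error"]
        data.frame(log2fc = co / ln2, se = se / ln2,
                   wald_p = 2 * stats::pnorm(-abs(co / se)),
                   dispersion = dispersions[g], basemean = bm,
                   flagged = FALSE)
    })
    out <- do.call(rbind, res)
    out <- cbind(gene = rownames(counts), out)
    rownames(out) <- NULL
    out
}

#' Rank genes by negative binomial log2 fold change
#'
#' Runs size factors, dispersion estimation and the NB Wald GLM, then ranks
#' genes by log2 fold change decreasing (ties broken lexicographically by
#' gene id) into the same ranked-list container the survival mode uses, so
#' the enrichment engine is shared. Genes with non-finite fold changes are
#' excluded and recorded; flagged (pseudo-mean) fold changes are retained.
#'
#' @inheritParams nbWaldLfc
#' @param verbose message the exclusion count.
#' @return A [CoxRankedList-class] with mode "lfc".
#' @export
rankByLfc <- function(counts, condition, sizeFactors = NULL,
                      dispersions = NULL, pairs = NULL, verbose = TRUE) {
    fits <- nbWaldLfc(counts, condition, sizeFactors = sizeFactors,
                      dispersions = dispersions, pairs = pairs)
    ok <- is.finite(fits$log2fc)
    if (sum(ok) < 2L) stop("fewer than 2 genes with a usable fold change")
    if (verbose && any(!ok))
        message("rankByLfc: excluded ", sum(!ok),
                " gene(s) with non-finite fold change")
    det <- data.frame(gene = fits$gene[ok], stat = fits$log2fc[ok],
                      se = fits$se[ok], p = fits$wald_p[ok],
                      dispersion = fits$dispersion[ok],
                      basemean = fits$basemean[ok],
                      flagged = fits$flagged[ok])
    CoxRankedList(stats::setNames(fits$log2fc[ok], fits$gene[ok]),
                  mode = "lfc", excluded = fits$gene[!ok], details = det)
}
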