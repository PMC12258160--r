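# Cox proportional-hazards partial likelihood machinery.
#
# The per-gene model is h(t | x) = h0(t) exp(beta * x): beta is the log
# hazard ratio for a one-unit increase in normalized expression, and the
# baseline hazard h0 is profiled out by the partial likelihood. Fitting is
# Newton-Raphson with step-halving on the Efron- (default) or
# Breslow-corrected partial log-likelihood. The risk-set bookkeeping that
# does not depend on beta is precomputed once per dataset (coxSchedule) and
# shared across the thousands of per-gene fits.

#' Precompute the risk-set schedule for a survival dataset
#'
#' Sorts samples by decreasing follow-up time and records, for every event
#' time, the risk set boundary and the tied-event structure needed by the
#' Efron correction. The schedule depends only on (time, status), so it is
#' computed once and reused across all per-gene Cox fits.
#'
#' @param time positive follow-up times.
#' @param status 0/1 event indicators (1 = event).
#' @return An opaque list consumed by [coxPartialFit()].
#' @export
coxSchedule <- function(time, status) {
    stopifnot(length(time) == length(status), all(time > 0),
              all(status %in% c(0, 1)))
    if (sum(status) == 0)
        stop("no events in the survival data; Cox fitting is impossible")
    ord <- order(-time)
    ts <- time[ord]
    ds <- status[ord] == 1
    runs <- rle(ts)
    ends <- cumsum(runs$lengths)
    # runs that contain at least one event become event groups
    runId <- rep(seq_along(runs$lengths), runs$lengths)
    evPos <- which(ds)
    evRun <- runId[evPos]
    grpRuns <- sort(unique(evRun))
    G <- length(grpRuns)
    d <- as.integer(table(factor(evRun, levels = grpRuns)))
    blockEnd <- ends[grpRuns]
    eventGroup <- match(evRun, grpRuns)
    # order events by group so rowsum() output aligns with group id 1..G
    o <- order(eventGroup)
    evPos <- evPos[o]
    eventGroup <- eventGroup[o]
    gRep <- rep(seq_len(G), d)
    fracEfron <- unlist(lapply(d, function(k) (seq_len(k) - 1) / k),
                        use.names = FALSE)
    list(ord = ord, n = length(ts), eventsIdx = evPos,
         eventGroup = eventGroup, blockEnd = blockEnd, d = d,
         gRep = gRep, fracEfron = fracEfron, nEvents = length(evPos))
}

# Partial log-likelihood, score and observed information at beta.
# Xs: samples-sorted design (n x p); frac: per-expanded-event Efron fraction.
.coxLLik <- function(beta, Xs, sch, frac, pairs) {
    p <- ncol(Xs)
    eta <- drop(Xs %*% beta)
    M <- max(eta)
    w <- exp(eta - M)
    WX <- Xs * w
    cum0 <- cumsum(w)
    cum1 <- apply(WX, 2L, cumsum)
    if (p == 1L) dim(cum1) <- c(sch$n, 1L)
    WXX <- WX[, pairs[, 1L], drop = FALSE] * Xs[, pairs[, 2L], drop = FALSE]
    cum2 <- apply(WXX, 2L, cumsum)
    if (ncol(pairs) == 2L && nrow(pairs) == 1L) dim(cum2) <- c(sch$n, 1L)
    ev <- sch$eventsIdx
    rs0 <- cum0[sch$blockEnd]
    rs1 <- cum1[sch$blockEnd, , drop = FALSE]
    rs2 <- cum2[sch$blockEnd, , drop = FALSE]
    s0d <- drop(rowsum(w[ev], sch$eventGroup))
    s1d <- rowsum(WX[ev, , drop = FALSE], sch$eventGroup)
    s2d <- rowsum(WXX[ev, , drop = FALSE], sch$eventGroup)
    g <- sch$gRep
    denom <- rs0[g] - frac * s0d[g]
    num1 <- rs1[g, , drop = FALSE] - frac * s1d[g, , drop = FALSE]
    num2 <- rs2[g, , drop = FALSE] - frac * s2d[g, , drop = FALSE]
    if (any(denom <= 0) || any(!is.finite(denom)))
        return(list(ll = -Inf))
    xbar <- num1 / denom
    ll <- sum(eta[ev]) - sum(log(denom)) - length(denom) * M
    U <- colSums(Xs[ev, , drop = FALSE]) - colSums(xbar)
    Ivals <- colSums(num2 / denom) -
        colSums(xbar[, pairs[, 1L], drop = FALSE] *
                xbar[, pairs[, 2L], drop = FALSE])
    info <- matrix(0, p, p)
    info[pairs] <- Ivals
    info[pairs[, c(2L, 1L), drop = FALSE]] <- Ivals
    list(ll = ll, U = U, info = info)
}

#' Fit a Cox proportional-hazards model by partial likelihood
#'
#' Newton-Raphson maximization with step-halving. Convergence is declared
#' when the relative change of the partial log-likelihood falls below
#' \code{tol}; fits reaching \code{maxIter} or wandering past |beta| = 15
#' on the first coefficient (quasi-separation) are flagged non-converged.
#'
#' @param X n x p design matrix (the gene of interest in column 1, shared
#'   covariates after it). A plain vector is treated as a single column.
#' @param time,status survival outcome (see [coxSchedule()]).
#' @param ties "efron" (default, matches the survival-package default) or
#'   "breslow".
#' @param init starting coefficients (default all zero).
#' @param maxIter,tol Newton-Raphson controls.
#' @param schedule optional precomputed [coxSchedule()] for (time, status).
#' @return list with elements \code{beta}, \code{se}, \code{z}, \code{p}
#'   (Wald), \code{loglik}, \code{loglik0}, \code{converged},
#'   \code{informative}, \code{iter}, \code{nEvents}.
#' @examples
#' time <- c(5, 8, 2, 9, 4, 7); status <- c(1, 1, 1, 0, 1, 1)
#' x <- c(1, 0, 1, 0, 1, 0)
#' coxPartialFit(x, time, status)$beta
#' @export
coxPartialFit <- function(X, time, status, ties = c("efron", "breslow"),
                          init = NULL, maxIter = 25L, tol = 1e-9,
                          schedule = NULL) {
    ties <- match.arg(ties)
    if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
    X <- as.matrix(X)
    p <- ncol(X)
    if (is.null(schedule)) schedule <- coxSchedule(time, status)
    sch <- schedule
    stopifnot(nrow(X) == sch$n)
    out0 <- list(beta = rep(0, p), se = rep(NA_real_, p),
                 z = rep(NA_real_, p), p = rep(NA_real_, p),
                 loglik = NA_real_, loglik0 = NA_real_, converged = FALSE,
                 informative = FALSE, iter = 0L, nEvents = sch$nEvents)
    if (all(apply(X, 2L, function(v) diff(range(v)) == 0)))
        return(out0)  # no covariate information at all
    Xs <- X[sch$ord, , drop = FALSE]
    frac <- if (ties == "efron") sch$fracEfron else rep(0, length(sch$fracEfron))
    ut <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
    pairs <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
    beta <- if (is.null(init)) rep(0, p) else as.numeric(init)
    cur <- .coxLLik(beta, Xs, sch, frac, pairs)
    ll0 <- .coxLLik(rep(0, p), Xs, sch, frac, pairs)$ll
    converged <- FALSE
    iter <- 0L
    while (iter < maxIter) {
        iter <- iter + 1L
        step <- tryCatch(solve(cur$info, cur$U), error = function(e) NULL)
        if (is.null(step) || any(!is.finite(step))) {
            out0$loglik0 <- ll0
            return(out0)  # singular information: non-informative fit
        }
        cand <- beta + step
        new <- .coxLLik(cand, Xs, sch, frac, pairs)
        halves <- 0L
        while ((!is.finite(new$ll) || new$ll < cur$ll) && halves < 20L) {
            halves <- halves + 1L
            cand <- beta + step / 2^halves
            new <- .coxLLik(cand, Xs, sch, frac, pairs)
        }
        done <- is.finite(new$ll) &&
            abs(new$ll - cur$ll) < tol * (abs(cur$ll) + 1)
        beta <- cand
        cur <- new
        if (done) { converged <- TRUE; break }
    }
    if (abs(beta[1L]) > 15) converged <- FALSE  # quasi-separation
    covb <- tryCatch(solve(cur$info), error = function(e) NULL)
    se <- if (is.null(covb)) rep(NA_real_, p) else sqrt(pmax(diag(covb), 0))
    z <- beta / se
    list(beta = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
         loglik = cur$ll, loglik0 = ll0, converged = converged,
         informative = TRUE, iter = iter, nEvents = sch$nEvents)
}

#' Cox fit for a single gene
#'
#' Fits h(t | x) = h0(t) exp(beta x + gamma' z) for one gene's normalized
#' expression x and optional shared covariates z, and reports the gene
#' coefficient. A constant expression vector carries no likelihood
#' information and is returned with beta = 0 and \code{informative = FALSE}.
#'
#' @param expr per-sample normalized expression (one gene).
#' @param time,status survival outcome.
#' @param covariates optional numeric matrix/data.frame of per-sample
#'   covariates shared across genes.
#' @inheritParams coxPartialFit
#' @return list: \code{beta}, \code{se}, \code{z}, \code{p}, \code{loglik},
#'   \code{converged}, \code{informative}, \code{nEvents}.
#' @examples
#' fitCoxGene(c(2, 1, 4, 3, 6, 5), time = c(3, 1, 6, 2, 9, 5),
#'            status = c(1, 1, 1, 1, 0, 1))
#' @export
fitCoxGene <- function(expr, time, status, covariates = NULL,
                       ties = c("efron", "breslow"), maxIter = 25L,
                       tol = 1e-9, schedule = NULL) {
    ties <- match.arg(ties)
    if (diff(range(expr)) == 0) {
        sch <- if (is.null(schedule)) coxSchedule(time, status) else schedule
        return(list(beta = 0, se = NA_real_, z = NA_real_, p = NA_real_,
                    loglik = NA_real_, converged = FALSE,
                    informative = FALSE, nEvents = sch$nEvents))
    }
    X <- if (is.null(covariates)) matrix(expr, ncol = 1L)
         else cbind(expr, as.matrix(covariates))
    fit <- coxPartialFit(X, time, status, ties = ties, maxIter = maxIter,
                         tol = tol, schedule = schedule)
    list(beta = fit$beta[1L], se = fit$se[1L], z = fit$z[1L], p = fit$p[1L],
         loglik = fit$loglik, converged = fit$converged,
         informative = fit$informative, nEvents = fit$nEvents)
}

#' Rank genes by Cox log hazard ratio
#'
#' Fits one Cox model per gene on normalized (log2-CPM) expression, with an
#' optional shared covariate block, and ranks genes by the estimated log
#' hazard ratio, decreasing: the top of the list is most associated with
#' mortality, the bottom with survival. Non-converged, quasi-separated and
#' non-informative fits are excluded from the ranking (not clipped: a
#' clipped beta of +/-15 would dominate the list extremes) and the exclusion
#' fraction is reported. Ties are broken lexicographically by gene id.
#'
#' @param norm gene x sample matrix of normalized expression (e.g. the
#'   \code{logcpm} element of [logcpmVoom()]), or a [logcpmVoom()] result.
#' @param time,status survival outcome aligned to the matrix columns.
#' @param covariates optional per-sample numeric covariates included in
#'   every per-gene fit.
#' @inheritParams coxPartialFit
#' @param verbose message the exclusion count.
#' @return A [CoxRankedList-class] with mode "lhr".
#' @examples
#' sim <- simulateSurvivalDataset(n_samples = 60, n_genes = 40, seed = 1)
#' nm <- logcpmVoom(sim$counts)
#' rl <- rankByLhr(nm, sim$survival$time, sim$survival$status)
#' head(rankStats(rl))
#' @export
rankByLhr <- function(norm, time, status, covariates = NULL,
                      ties = c("efron", "breslow"), maxIter = 25L,
                      tol = 1e-9, verbose = TRUE) {
    ties <- match.arg(ties)
    if (is.list(norm) && !is.null(norm$logcpm)) norm <- norm$logcpm
    stopifnot(is.matrix(norm), ncol(norm) == length(time),
              length(time) == length(status))
    if (is.null(rownames(norm)))
        stop("normalized matrix must carry gene identifiers as rownames")
    sch <- coxSchedule(time, status)
    covm <- if (is.null(covariates)) NULL else as.matrix(covariates)
    G <- nrow(norm)
    beta <- se <- z <- pv <- rep(NA_real_, G)
    ok <- logical(G)
    for (g in seq_len(G)) {
        f <- fitCoxGene(norm[g, ], time, status, covariates = covm,
                        ties = ties, maxIter = maxIter, tol = tol,
                        schedule = sch)
        ok[g] <- f$converged && f$informative
        beta[g] <- f$beta; se[g] <- f$se; z[g] <- f$z; pv[g] <- f$p
    }
    genes <- rownames(norm)
    if (sum(ok) < 2L)
        stop("fewer than 2 genes produced a usable Cox fit")
    if (verbose && any(!ok))
        message(sprintf("rankByLhr: excluded %d/%d genes (%.2f%%) with %s",
                        sum(!ok), G, 100 * mean(!ok),
                        "non-converged or non-informative fits"))
    det <- data.frame(gene = genes[ok], stat = beta[ok], se = se[ok],
                      z = z[ok], p = pv[ok])
    CoxRankedList(stats = stats::setNames(beta[ok], genes[ok]), mode = "lhr",
                  excluded = genes[!ok], details = det)
}
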