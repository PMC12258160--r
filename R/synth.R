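# Synthetic-data generators emulating a TCGA-like renal carcinoma cohort,
# so every pipeline stage is testable without downloads: negative binomial
# counts over log-normally spread gene means, censored survival times
# generated from a proportional-hazards model with an exponential baseline,
# planted hazard-associated pathways, and a matching two-condition
# fold-change scenario. The ground truth is returned separately and never
# leaks into the observable tables.

.logcpm <- function(counts) {
    lib <- colSums(counts)
    log2(sweep(counts + 0.5, 2L, (lib + 1) / 1e6, "/"))
}

#' Simulate a censored-survival RNA-seq dataset with planted pathways
#'
#' Counts are negative binomial with gene means drawn log-normally (median
#' 50 reads, spread typical of bulk RNA-seq) and mild per-sample library
#' size variation. Survival times follow a proportional-hazards model with
#' a constant (exponential) baseline hazard: each sample's hazard is
#' multiplied by exp(sum of beta_true times its standardized log2-CPM) over
#' the signal genes, so \code{effect_beta} reads as a log hazard ratio per
#' standard deviation of normalized expression. Censoring is independent
#' uniform, with its upper bound calibrated numerically so the realized
#' censoring fraction lands on \code{censor_target}; the default 0.69
#' mirrors a cohort with roughly 360 of 520 subjects censored. The first
#' \code{n_signal_pathways} gene sets contain exactly the signal genes;
#' remaining pathways are random draws from the gene universe.
#'
#' @param n_samples,n_genes cohort and transcriptome size (defaults 520 and
#'   2000).
#' @param n_pathways,pathway_size gene set collection shape.
#' @param n_signal_pathways number of planted hazard-associated pathways
#'   (their genes get \code{effect_beta}; set 0 for a global null).
#' @param effect_beta log hazard ratio per SD of normalized expression for
#'   signal genes.
#' @param beta_true optional length-\code{n_genes} vector of per-gene log
#'   hazard ratios, overriding the pathway-based assignment (for
#'   calibration studies).
#' @param censor_target target censoring fraction in [0, 0.9].
#' @param nb_dispersion common NB dispersion of the counts.
#' @param baseline_hazard constant baseline hazard rate (time unit scale
#'   only; days-like with the default).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return list: \code{counts} (gene x sample matrix), \code{survival}
#'   (data.frame sample/time/status), \code{pathways} (named list, GMT
#'   semantics), \code{truth} (beta_true per SD, signal genes/pathways,
#'   per-gene log-CPM SD used for standardization, realized censoring,
#'   parameters).
#' @examples
#' sim <- simulateSurvivalDataset(n_samples = 40, n_genes = 60, seed = 1)
#' mean(sim$survival$status == 0)  # close to the 0.69 censoring target
#' @export
simulateSurvivalDataset <- function(n_samples = 520, n_genes = 2000,
                                    n_pathways = 50, pathway_size = 20,
                                    n_signal_pathways = 1,
                                    effect_beta = 0.8, beta_true = NULL,
                                    censor_target = 0.69,
                                    nb_dispersion = 0.3,
                                    baseline_hazard = 0.002, seed = NULL) {
    stopifnot(pathway_size < n_genes, n_samples >= 4)
    if (censor_target < 0 || censor_target > 0.9)
        stop("censor_target must lie in [0, 0.9]")
    if (n_signal_pathways * pathway_size > n_genes)
        stop("more signal genes requested than genes available")
    if (!is.null(seed)) set.seed(seed)
    genes <- sprintf("g%05d", seq_len(n_genes))
    samples <- sprintf("s%04d", seq_len(n_samples))
    mu <- exp(stats::rnorm(n_genes, log(50), 1.5))
    libf <- exp(stats::rnorm(n_samples, 0, 0.2))
    mum <- outer(mu, libf)
    counts <- if (nb_dispersion > 0)
        matrix(stats::rnbinom(n_genes * n_samples, mu = mum,
                              size = 1 / nb_dispersion),
               n_genes, n_samples)
    else
        matrix(stats::rpois(n_genes * n_samples, mum), n_genes, n_samples)
    dimnames(counts) <- list(genes, samples)

    z <- .logcpm(counts)
    sds <- apply(z, 1L, stats::sd)
    z <- (z - rowMeans(z)) / ifelse(sds > 0, sds, 1)
    z[sds == 0, ] <- 0

    signalGenes <- character()
    signalPathways <- character()
    pwNames <- sprintf("PW_%03d", seq_len(n_pathways))
    pathways <- vector("list", n_pathways)
    names(pathways) <- pwNames
    if (n_signal_pathways > 0) {
        sg <- sample(genes, n_signal_pathways * pathway_size)
        for (j in seq_len(n_signal_pathways))
            pathways[[j]] <- sg[((j - 1) * pathway_size + 1):(j * pathway_size)]
        signalGenes <- sg
        signalPathways <- pwNames[seq_len(n_signal_pathways)]
    }
    for (j in seq_len(n_pathways))
        if (is.null(pathways[[j]])) pathways[[j]] <- sample(genes, pathway_size)
    attr(pathways, "descriptions") <-
        stats::setNames(ifelse(pwNames %in% signalPathways,
                               "planted hazard-associated set",
                               "random set"), pwNames)

    if (is.null(beta_true)) {
        beta_true <- stats::setNames(rep(0, n_genes), genes)
        beta_true[signalGenes] <- effect_beta
    } else {
        stopifnot(length(beta_true) == n_genes)
        beta_true <- stats::setNames(as.numeric(beta_true), genes)
    }

    lp <- drop(crossprod(z, beta_true))
    tev <- stats::rexp(n_samples) / (baseline_hazard * exp(lp))
    if (censor_target == 0) {
        time <- tev
        status <- rep(1, n_samples)
        cmax <- Inf
    } else {
        f <- function(lc) mean(pmin(tev / exp(lc), 1)) - censor_target
        lc <- stats::uniroot(f, lower = log(min(tev)) - 20,
                             upper = log(max(tev)) + 20)$root
        cmax <- exp(lc)
        cens <- stats::runif(n_samples, 0, cmax)
        status <- as.numeric(tev <= cens)
        time <- pmin(tev, cens)
    }
    survival <- data.frame(sample = samples, time = time, status = status,
                           stringsAsFactors = FALSE)
    truth <- list(beta_true = beta_true, signalGenes = signalGenes,
                  signalPathways = signalPathways, logcpm_sd = sds,
                  censoring_realized = mean(status == 0), cmax = cmax,
                  params = list(n_samples = n_samples, n_genes = n_genes,
                                n_pathways = n_pathways,
                                pathway_size = pathway_size,
                                n_signal_pathways = n_signal_pathways,
                                effect_beta = effect_beta,
                                censor_target = censor_target,
                                nb_dispersion = nb_dispersion,
                                baseline_hazard = baseline_hazard,
                                seed = seed))
    list(counts = counts, survival = survival, pathways = pathways,
         truth = truth)
}

#' Simulate a two-condition (case-control) RNA-seq dataset
#'
#' Negative binomial counts with \code{n_de} genes shifted by plus or minus
#' \code{lfc_magnitude} in log2 mean in the case group (half up, half
#' down). With \code{paired = TRUE} each case-control pair shares a random
#' baseline expression factor, emulating matched tumor/normal tissue.
#'
#' @param n_per_group samples per condition.
#' @param n_genes,n_de transcriptome size and number of shifted genes.
#' @param lfc_magnitude absolute planted log2 fold change.
#' @param nb_dispersion common NB dispersion.
#' @param paired share a per-pair baseline between matched samples.
#' @param seed integer seed.
#' @return list: \code{counts}, \code{condition} (factor control/case
#'   aligned to columns), \code{pairs} (or NULL), \code{truth} (per-gene
#'   true log2 fold change, DE genes, parameters).
#' @export
simulateCaseControlDataset <- function(n_per_group = 50, n_genes = 2000,
                                       n_de = 100, lfc_magnitude = 1,
                                       nb_dispersion = 0.3, paired = FALSE,
                                       seed = NULL) {
    stopifnot(n_de <= n_genes, n_per_group >= 2)
    if (!is.null(seed)) set.seed(seed)
    genes <- sprintf("g%05d", seq_len(n_genes))
    n <- 2L * n_per_group
    samples <- sprintf("s%04d", seq_len(n))
    condition <- factor(rep(c("control", "case"), each = n_per_group),
                        levels = c("control", "case"))
    mu <- exp(stats::rnorm(n_genes, log(50), 1.5))
    lfc <- stats::setNames(rep(0, n_genes), genes)
    if (n_de > 0) {
        de <- sample(genes, n_de)
        lfc[de] <- rep_len(c(1, -1), n_de) * lfc_magnitude
    } else de <- character()
    mum <- outer(mu, rep(1, n))
    mum[, condition == "case"] <- mum[, condition == "case"] * 2^lfc
    pairs <- NULL
    if (paired) {
        pairs <- rep(sprintf("p%03d", seq_len(n_per_group)), times = 2L)
        pf <- exp(stats::rnorm(n_per_group, 0, 0.3))
        mum <- sweep(mum, 2L, pf[match(pairs, unique(pairs))], "*")
    }
    counts <- if (nb_dispersion > 0)
        matrix(stats::rnbinom(n_genes * n, mu = mum,
                              size = 1 / nb_dispersion), n_genes, n)
    else
        matrix(stats::rpois(n_genes * n, mum), n_genes, n)
    dimnames(counts) <- list(genes, samples)
    truth <- list(lfc_true = lfc, deGenes = de,
                  params = list(n_per_group = n_per_group,
                                n_genes = n_genes, n_de = n_de,
                                lfc_magnitude = lfc_magnitude,
                                nb_dispersion = nb_dispersion,
                                paired = paired, seed = seed))
    list(counts = counts, condition = condition, pairs = pairs,
         truth = truth)
}
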