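# End-to-end pipelines and the command-line front end. The pipelines bind
# the stages (filter -> normalize -> rank -> enrich -> report), log record
# counts at each stage, and serialize the resolved configuration next to
# every output so any run can be regenerated exactly. The CLI is a thin
# subcommand dispatcher over these functions; intermediate ranked lists are
# first-class files, so externally ranked lists can be injected (preranked
# mode).

.writeConfig <- function(outDir, config) {
    config$package_version <- as.character(utils::packageVersion("survGSEA"))
    jsonlite::write_json(config, file.path(outDir, "config.json"),
                         auto_unbox = TRUE, null = "null", digits = NA,
                         pretty = TRUE)
}

.resolveCollection <- function(geneSets)
    if (is.character(geneSets)) readGmt(geneSets) else geneSets

.writeRunOutputs <- function(outDir, ranked, results, top, config) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeRankedList(ranked, file.path(outDir, "ranked.csv"), "csv")
    writeRankedList(ranked, file.path(outDir, "ranked.rnk"), "rnk")
    writeEnrichmentTable(results, file.path(outDir, "enrichment.csv"))
    writeEnrichmentTable(top$positive, file.path(outDir, "top_positive.csv"))
    writeEnrichmentTable(top$negative, file.path(outDir, "top_negative.csv"))
    .writeConfig(outDir, config)
}

#' Run the survival-based enrichment pipeline
#'
#' Filter low-expression genes, normalize to log2-CPM (voom), fit one Cox
#' model per gene, rank genes by log hazard ratio, test the gene set
#' collection for enrichment, and extract the top mortality- and
#' survival-associated pathways. When \code{outDir} is given, the ranked
#' list (CSV and RNK), the enrichment table, the top tables and a
#' config.json snapshot sufficient to reproduce the run are written there.
#'
#' @param counts gene x sample count matrix, or a path to a delimited
#'   counts file (orientation auto-detected against the survival samples).
#' @param survival data.frame from [readSurvival()], or a path to the
#'   survival file.
#' @param geneSets named list of gene sets, or a path to a GMT file.
#' @param outDir optional output directory.
#' @param minMean low-expression filter threshold (mean reads/sample).
#' @param covariates character vector of survival-table covariate columns
#'   to include in every Cox fit.
#' @param ties,minSize,maxSize,nperm,npermMax,alpha,k,exponent stage
#'   parameters (see [rankByLhr()], [runEnrichment()], [topTables()]).
#' @param seed integer seed; same seed and inputs give a bit-identical
#'   enrichment table.
#' @param timeCol,statusCol,delimiter survival file parsing options (used
#'   only when \code{survival} is a path).
#' @return invisibly, a list: \code{experiment}, \code{ranked},
#'   \code{results}, \code{top}.
#' @export
runSGSEA <- function(counts, survival, geneSets, outDir = NULL,
                     minMean = 0.1, covariates = NULL, ties = "efron",
                     minSize = 3, maxSize = 500, nperm = 1000,
                     npermMax = 1e6, alpha = 0.15, k = 10, exponent = 1,
                     seed = NULL, timeCol = "time", statusCol = "status",
                     delimiter = "auto") {
    config <- list(mode = "sgsea", minMean = minMean,
                   covariates = covariates, ties = ties, minSize = minSize,
                   maxSize = maxSize, nperm = nperm, npermMax = npermMax,
                   alpha = alpha, k = k, exponent = exponent, seed = seed,
                   counts = if (is.character(counts)) counts else "in-memory",
                   survival = if (is.character(survival)) survival
                              else "in-memory",
                   geneSets = if (is.character(geneSets)) geneSets
                              else "in-memory")
    if (is.character(survival))
        survival <- readSurvival(survival, timeCol = timeCol,
                                 statusCol = statusCol,
                                 covariateCols = covariates,
                                 delimiter = delimiter)
    if (is.character(counts))
        counts <- readCounts(counts, orientation = "auto",
                             delimiter = delimiter,
                             sampleIds = survival$sample)
    collection <- .resolveCollection(geneSets)
    se <- SurvivalExperiment(counts, survival)
    message(sprintf("sgsea: %d genes x %d samples, %d events", nrow(se),
                    ncol(se), nEvents(se)))
    se <- filterLowExpression(se, minMean = minMean)
    nm <- logcpmVoom(se)
    covm <- if (is.null(covariates)) NULL
            else as.matrix(as.data.frame(colData(se))[, covariates,
                                                      drop = FALSE])
    ranked <- rankByLhr(nm, survTime(se), survStatus(se),
                        covariates = covm, ties = ties)
    message(sprintf("sgsea: ranked %d genes by log hazard ratio",
                    length(ranked)))
    results <- runEnrichment(ranked, collection, minSize = minSize,
                             maxSize = maxSize, nperm = nperm,
                             npermMax = npermMax, seed = seed,
                             alpha = alpha, exponent = exponent)
    message(sprintf("sgsea: %d pathways tested, %d significant at padj < %g",
                    nrow(enrichTable(results)),
                    nrow(significant(results)), alpha))
    top <- topTables(results, k = k, alpha = alpha)
    if (!is.null(outDir))
        .writeRunOutputs(outDir, ranked, results, top, config)
    invisible(list(experiment = se, ranked = ranked, results = results,
                   top = top))
}

#' Run the fold-change-based enrichment pipeline
#'
#' Standard case-vs-control enrichment sharing the engine with the survival
#' mode: filter, median-of-ratios size factors, NB dispersion and Wald log2
#' fold changes, fold-change ranking, enrichment, top tables.
#'
#' @param counts gene x sample count matrix or path.
#' @param metadata data.frame with a \code{sample} column plus the
#'   condition (and optional pairing) columns, or a path to such a file.
#' @param geneSets named list of gene sets, or GMT path.
#' @param conditionCol,pairedCol metadata column names; the condition must
#'   have exactly two levels (fold changes are second level vs first).
#' @inheritParams runSGSEA
#' @return invisibly, a list: \code{ranked}, \code{results}, \code{top},
#'   \code{fits}.
#' @export
runGSEA <- function(counts, metadata, geneSets, conditionCol = "condition",
                    pairedCol = NULL, outDir = NULL, minMean = 0.1,
                    minSize = 3, maxSize = 500, nperm = 1000,
                    npermMax = 1e6, alpha = 0.15, k = 10, exponent = 1,
                    seed = NULL, delimiter = "auto") {
    config <- list(mode = "gsea", conditionCol = conditionCol,
                   pairedCol = pairedCol, minMean = minMean,
                   minSize = minSize, maxSize = maxSize, nperm = nperm,
                   npermMax = npermMax, alpha = alpha, k = k,
                   exponent = exponent, seed = seed)
    if (is.character(metadata)) {
        md <- .readDelim(metadata, delimiter)
        metadata <- data.frame(sample = rownames(md), md,
                               stringsAsFactors = FALSE,
                               check.names = FALSE)
    }
    if (!conditionCol %in% colnames(metadata))
        stop("metadata lacks condition column '", conditionCol, "'")
    if (is.character(counts))
        counts <- readCounts(counts, orientation = "auto",
                             delimiter = delimiter,
                             sampleIds = metadata$sample)
    collection <- .resolveCollection(geneSets)
    shared <- intersect(colnames(counts), metadata$sample)
    if (length(shared) < 4L)
        stop("fewer than 4 samples shared between counts and metadata")
    counts <- counts[, shared, drop = FALSE]
    metadata <- metadata[match(shared, metadata$sample), , drop = FALSE]
    condition <- factor(metadata[[conditionCol]])
    pairs <- if (is.null(pairedCol)) NULL else metadata[[pairedCol]]
    counts <- filterLowExpression(counts, minMean = minMean)
    ranked <- rankByLfc(counts, condition, pairs = pairs)
    message(sprintf("gsea: ranked %d genes by log2 fold change (%s vs %s)",
                    length(ranked), levels(condition)[2L],
                    levels(condition)[1L]))
    results <- runEnrichment(ranked, collection, minSize = minSize,
                             maxSize = maxSize, nperm = nperm,
                             npermMax = npermMax, seed = seed,
                             alpha = alpha, exponent = exponent)
    message(sprintf("gsea: %d pathways tested, %d significant at padj < %g",
                    nrow(enrichTable(results)),
                    nrow(significant(results)), alpha))
    top <- topTables(results, k = k, alpha = alpha)
    if (!is.null(outDir))
        .writeRunOutputs(outDir, ranked, results, top, config)
    invisible(list(ranked = ranked, results = results, top = top))
}

.parseFlags <- function(args) {
    out <- list()
    i <- 1L
    while (i <= length(args)) {
        a <- args[[i]]
        if (!startsWith(a, "--")) stop("unexpected argument: ", a)
        key <- gsub("-", "_", sub("^--", "", a))
        if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
            out[[key]] <- TRUE
        } else {
            i <- i + 1L
            out[[key]] <- args[[i]]
        }
        i <- i + 1L
    }
    out
}

.flagNum <- function(fl, key, default) {
    if (is.null(fl[[key]])) default else as.numeric(fl[[key]])
}
.flagChr <- function(fl, key, default = NULL) {
    if (is.null(fl[[key]])) default else as.character(fl[[key]])
}

#' Command-line entry point
#'
#' Dispatches the subcommands \code{sgsea}, \code{gsea}, \code{audit-fdr},
#' \code{compare}, \code{simulate} and \code{plot} over the pipeline
#' functions. Installed alongside the package as the executable script
#' \code{inst/scripts/survgsea}. All tables are CSV, machine summaries are
#' JSON, logs go to stderr via \code{message()}.
#'
#' @param argv character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return invisibly, the subcommand's result object.
#' @export
sgseaMain <- function(argv = commandArgs(trailingOnly = TRUE)) {
    if (!length(argv))
        stop("usage: survgsea <sgsea|gsea|audit-fdr|compare|simulate|plot> ",
             "--help for flags")
    cmd <- argv[[1L]]
    fl <- .parseFlags(argv[-1L])
    seed <- if (is.null(fl$seed)) NULL else as.integer(fl$seed)
    res <- switch(cmd,
        "sgsea" = runSGSEA(
            counts = .flagChr(fl, "counts"),
            survival = .flagChr(fl, "survival"),
            geneSets = .flagChr(fl, "gmt"),
            outDir = .flagChr(fl, "out", "sgsea_out"),
            minMean = .flagNum(fl, "min_mean", 0.1),
            covariates = if (is.null(fl$covariates)) NULL
                         else strsplit(fl$covariates, ",")[[1L]],
            ties = .flagChr(fl, "ties", "efron"),
            minSize = .flagNum(fl, "min_size", 3),
            maxSize = .flagNum(fl, "max_size", 500),
            nperm = .flagNum(fl, "nperm", 1000),
            npermMax = .flagNum(fl, "nperm_max", 1e6),
            alpha = .flagNum(fl, "alpha", 0.15),
            seed = seed,
            timeCol = .flagChr(fl, "time_col", "time"),
            statusCol = .flagChr(fl, "status_col", "status")),
        "gsea" = runGSEA(
            counts = .flagChr(fl, "counts"),
            metadata = .flagChr(fl, "metadata"),
            geneSets = .flagChr(fl, "gmt"),
            conditionCol = .flagChr(fl, "condition_col", "condition"),
            pairedCol = .flagChr(fl, "paired_col"),
            outDir = .flagChr(fl, "out", "gsea_out"),
            minMean = .flagNum(fl, "min_mean", 0.1),
            minSize = .flagNum(fl, "min_size", 3),
            maxSize = .flagNum(fl, "max_size", 500),
            nperm = .flagNum(fl, "nperm", 1000),
            npermMax = .flagNum(fl, "nperm_max", 1e6),
            alpha = .flagNum(fl, "alpha", 0.15),
            seed = seed),
        "audit-fdr" = {
            counts <- readCounts(.flagChr(fl, "counts"),
                                 orientation = "genes_in_rows")
            surv <- readSurvival(.flagChr(fl, "survival"))
            audit <- permutationFdrAudit(
                counts, surv, readGmt(.flagChr(fl, "gmt")),
                B = .flagNum(fl, "B", 100),
                alpha = .flagNum(fl, "alpha", 0.15), seed = seed,
                minMean = .flagNum(fl, "min_mean", 0.1),
                nperm = .flagNum(fl, "nperm", 1000))
            out <- .flagChr(fl, "out", "fdr_audit.json")
            jsonlite::write_json(audit[c("perPathway", "average", "B",
                                         "alpha")],
                                 out, auto_unbox = TRUE, digits = NA)
            message("audit-fdr: average FDR ", signif(audit$average, 4),
                    " across ", length(audit$perPathway), " pathways -> ",
                    out)
            audit
        },
        "compare" = {
            part <- compareSignificant(
                readEnrichmentTable(.flagChr(fl, "res_a")),
                readEnrichmentTable(.flagChr(fl, "res_b")),
                alpha = .flagNum(fl, "alpha", 0.15))
            out <- .flagChr(fl, "out", "compare.json")
            jsonlite::write_json(part[c("both", "onlyA", "onlyB", "neither",
                                        "total")],
                                 out, auto_unbox = TRUE, digits = NA)
            message(sprintf("compare: both=%d onlyA=%d onlyB=%d neither=%d -> %s",
                            part$both, part$onlyA, part$onlyB,
                            part$neither, out))
            part
        },
        "simulate" = {
            outDir <- .flagChr(fl, "out", "sim_out")
            dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
            sim <- simulateSurvivalDataset(
                n_samples = .flagNum(fl, "n_samples", 520),
                n_genes = .flagNum(fl, "n_genes", 2000),
                n_pathways = .flagNum(fl, "n_pathways", 50),
                pathway_size = .flagNum(fl, "pathway_size", 20),
                n_signal_pathways = .flagNum(fl, "n_signal_pathways", 1),
                effect_beta = .flagNum(fl, "effect_beta", 0.8),
                censor_target = .flagNum(fl, "censor_target", 0.69),
                nb_dispersion = .flagNum(fl, "dispersion", 0.3),
                seed = seed)
            utils::write.csv(sim$counts, file.path(outDir, "counts.csv"))
            utils::write.csv(sim$survival, file.path(outDir, "survival.csv"),
                             row.names = FALSE)
            writeGmt(sim$pathways, file.path(outDir, "pathways.gmt"))
            jsonlite::write_json(
                sim$truth[c("beta_true", "signalGenes", "signalPathways",
                            "censoring_realized", "params")],
                file.path(outDir, "truth.json"), auto_unbox = TRUE,
                digits = NA)
            message("simulate: wrote counts.csv, survival.csv, ",
                    "pathways.gmt, truth.json to ", outDir)
            sim
        },
        "plot" = {
            ranked <- readRankedList(.flagChr(fl, "ranked"),
                                     dialect = .flagChr(fl, "dialect", "csv"))
            sets <- readGmt(.flagChr(fl, "gmt"))
            pw <- .flagChr(fl, "pathway")
            if (is.null(pw) || !pw %in% names(sets))
                stop("--pathway must name a set in the GMT file")
            p <- plotEnrichment(ranked, sets[[pw]], title = pw)
            out <- .flagChr(fl, "out", "enrichment_plot.png")
            ggplot2::ggsave(out, p, width = 7, height = 4, dpi = 150)
            message("plot: wrote ", out)
            p
        },
        stop("unknown subcommand: ", cmd))
    invisible(res)
}
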