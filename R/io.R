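# Readers and writers for the external formats the tool touches: delimited
# count matrices (either orientation), survival metadata, GMT gene set
# collections, ranked-list exports (CSV/RNK) and enrichment result tables.
# Gene and sample identifiers are opaque case-sensitive strings; the only
# renaming mechanism is an explicit id map.

.readDelim <- function(path, delimiter) {
    if (identical(delimiter, "auto")) {
        first <- readLines(path, n = 1L)
        delimiter <- if (grepl("\t", first)) "\t" else ","
    }
    utils::read.table(path, header = TRUE, sep = delimiter,
                      check.names = FALSE, stringsAsFactors = FALSE,
                      row.names = 1L, comment.char = "")
}

#' Read a count matrix from a delimited text file
#'
#' The file must carry a header of identifiers and a first column of
#' identifiers; the matrix is returned in canonical gene x sample
#' orientation regardless of how it is stored. With
#' \code{orientation = "auto"} the axis whose labels overlap
#' \code{sampleIds} (e.g. the survival table's samples) is taken to be the
#' sample axis; an unresolvable tie is an error asking for an explicit
#' orientation, because silent transposition is the classic failure mode
#' for this input.
#'
#' @param path file path.
#' @param orientation one of "auto", "genes_in_rows", "samples_in_rows".
#' @param delimiter "," or "\t", or "auto" (sniff the first line).
#' @param sampleIds character vector of known sample ids, required for
#'   \code{orientation = "auto"}.
#' @return gene x sample numeric matrix of non-negative counts.
#' @export
readCounts <- function(path,
                       orientation = c("auto", "genes_in_rows",
                                       "samples_in_rows"),
                       delimiter = "auto", sampleIds = NULL) {
    orientation <- match.arg(orientation)
    df <- .readDelim(path, delimiter)
    m <- as.matrix(df)
    if (orientation == "auto") {
        if (is.null(sampleIds))
            stop("orientation = 'auto' requires 'sampleIds' to identify ",
                 "the sample axis")
        hitRows <- length(intersect(rownames(m), sampleIds))
        hitCols <- length(intersect(colnames(m), sampleIds))
        if (hitRows == hitCols)
            stop("cannot auto-detect orientation (", hitRows, " row and ",
                 hitCols, " column labels match the sample ids); pass ",
                 "orientation explicitly")
        orientation <- if (hitRows > hitCols) "samples_in_rows"
                       else "genes_in_rows"
    }
    if (orientation == "samples_in_rows") m <- t(m)
    for (axis in 1:2) {
        ids <- dimnames(m)[[axis]]
        if (anyDuplicated(ids))
            stop("duplicate ", c("gene", "sample")[axis], " identifiers: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    if (!is.numeric(m)) {
        bad <- which(is.na(suppressWarnings(
            matrix(as.numeric(m), nrow(m)))), arr.ind = TRUE)[1, ]
        stop("non-numeric count at gene '", rownames(m)[bad[1]],
             "', sample '", colnames(m)[bad[2]], "'")
    }
    if (any(m < 0 | !is.finite(m))) {
        bad <- which(m < 0 | !is.finite(m), arr.ind = TRUE)[1, ]
        stop("negative or non-finite count at gene '", rownames(m)[bad[1]],
             "', sample '", colnames(m)[bad[2]], "'")
    }
    m
}

.recodeStatus <- function(x) {
    if (is.logical(x)) return(as.numeric(x))
    if (is.numeric(x)) {
        if (all(x %in% c(0, 1), na.rm = TRUE)) return(x)
        stop("status values outside {0, 1}: ",
             paste(unique(x[!x %in% c(0, 1)]), collapse = ", "))
    }
    lx <- tolower(trimws(as.character(x)))
    map <- c("0" = 0, "1" = 1, "false" = 0, "true" = 1,
             "alive" = 0, "dead" = 1)
    if (!all(lx %in% names(map) | is.na(lx)))
        stop("unrecognized status labels: ",
             paste(unique(x[!lx %in% names(map)]), collapse = ", "),
             " (accepted: 0/1, TRUE/FALSE, alive/dead)")
    unname(map[lx])
}

#' Read per-sample survival metadata
#'
#' Loads a delimited table of time-to-event data. Rows with non-positive or
#' missing time, or missing status, are invalid inputs and are dropped with
#' a message. Status is recoded strictly to 0 (censored) / 1 (event);
#' accepted encodings are 0/1, TRUE/FALSE and case-insensitive alive/dead.
#'
#' @param path file path; first column holds sample identifiers.
#' @param timeCol,statusCol column names for follow-up time and event
#'   status.
#' @param covariateCols optional character vector of numeric covariate
#'   columns to retain.
#' @param delimiter "," or "\t", or "auto".
#' @return data.frame with columns \code{sample}, \code{time},
#'   \code{status}, then any covariates.
#' @export
readSurvival <- function(path, timeCol = "time", statusCol = "status",
                         covariateCols = NULL, delimiter = "auto") {
    df <- .readDelim(path, delimiter)
    need <- c(timeCol, statusCol, covariateCols)
    if (!all(need %in% colnames(df)))
        stop("missing column(s): ",
             paste(setdiff(need, colnames(df)), collapse = ", "))
    out <- data.frame(sample = rownames(df),
                      time = as.numeric(df[[timeCol]]),
                      status = .recodeStatus(df[[statusCol]]),
                      stringsAsFactors = FALSE)
    for (cc in covariateCols) out[[cc]] <- as.numeric(df[[cc]])
    bad <- is.na(out$time) | out$time <= 0 | is.na(out$status)
    if (any(bad))
        message("readSurvival: removed ", sum(bad),
                " sample(s) with invalid time or status")
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Read a GMT gene set collection
#'
#' Standard GMT semantics: one set per line, tab-separated fields
#' name / description / member genes. Duplicate members within a set are
#' deduplicated; duplicate set names are an error.
#'
#' @param path file path.
#' @return named list of character vectors (the gene sets), with a
#'   \code{"descriptions"} attribute (named character vector).
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
        out <- structure(list(), descriptions = character())
        return(out)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short))
        stop("GMT line ", short[1L], " has fewer than 3 tab-separated fields")
    nm <- vapply(fields, `[[`, character(1), 1L)
    if (anyDuplicated(nm))
        stop("duplicate gene set names: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    desc <- vapply(fields, `[[`, character(1), 2L)
    sets <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(sets) <- nm
    structure(sets, descriptions = stats::setNames(desc, nm))
}

#' Write a gene set collection in GMT format
#'
#' @param collection named list of character vectors, optionally with a
#'   \code{"descriptions"} attribute.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeGmt <- function(collection, path) {
    desc <- attr(collection, "descriptions")
    if (is.null(desc))
        desc <- stats::setNames(rep("na", length(collection)),
                                names(collection))
    lines <- vapply(names(collection), function(nm)
        paste(c(nm, desc[[nm]], collection[[nm]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a gene identifier map
#'
#' Two-column delimited table (header required) mapping one identifier
#' scheme to another, e.g. Entrez to HUGO symbols.
#'
#' @param path file path.
#' @param delimiter "," or "\t", or "auto".
#' @return named character vector: names are source ids, values target ids.
#' @export
readIdMap <- function(path, delimiter = "auto") {
    if (identical(delimiter, "auto")) {
        first <- readLines(path, n = 1L)
        delimiter <- if (grepl("\t", first)) "\t" else ","
    }
    df <- utils::read.table(path, header = TRUE, sep = delimiter,
                            stringsAsFactors = FALSE, check.names = FALSE)
    if (ncol(df) < 2L) stop("id map needs two columns (from, to)")
    stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Apply an identifier map to a count matrix
#'
#' Renames the gene axis using the map; genes without a mapping (or mapping
#' to a duplicate target) are dropped and the count reported. Applied
#' before enrichment so counts, ranked lists and gene sets share one
#' identifier scheme.
#'
#' @param counts gene x sample matrix.
#' @param map named character vector from [readIdMap()].
#' @return renamed matrix restricted to mapped genes.
#' @export
applyIdMap <- function(counts, map) {
    hit <- rownames(counts) %in% names(map)
    newIds <- unname(map[rownames(counts)[hit]])
    dup <- duplicated(newIds) | duplicated(newIds, fromLast = TRUE)
    keep <- which(hit)[!dup]
    dropped <- nrow(counts) - length(keep)
    if (dropped > 0)
        message("applyIdMap: dropped ", dropped,
                " unmapped or ambiguously mapped gene(s)")
    out <- counts[keep, , drop = FALSE]
    rownames(out) <- unname(map[rownames(counts)[keep]])
    out
}

#' Export a ranked gene list
#'
#' CSV dialect: header \code{gene,statistic}, rows in rank order. RNK
#' dialect: two tab-separated columns, no header (the preranked-GSEA
#' interchange format). A write/read round trip restores order exactly and
#' values to at least 1e-9.
#'
#' @param ranked a [CoxRankedList-class].
#' @param path output path.
#' @param dialect "csv" or "rnk".
#' @return invisibly, the path.
#' @export
writeRankedList <- function(ranked, path, dialect = c("csv", "rnk")) {
    dialect <- match.arg(dialect)
    stopifnot(is(ranked, "CoxRankedList"), length(ranked) > 0)
    df <- data.frame(gene = geneIds(ranked),
                     statistic = unname(rankStats(ranked)))
    if (dialect == "csv")
        utils::write.table(df, path, sep = ",", row.names = FALSE,
                           col.names = TRUE, quote = FALSE)
    else
        utils::write.table(df, path, sep = "\t", row.names = FALSE,
                           col.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a ranked gene list written by [writeRankedList()]
#'
#' @param path file path.
#' @param dialect "csv" (header) or "rnk" (headerless, tab-separated).
#' @param mode ranking mode tag to attach.
#' @return A [CoxRankedList-class].
#' @export
readRankedList <- function(path, dialect = c("csv", "rnk"),
                           mode = "external") {
    dialect <- match.arg(dialect)
    df <- if (dialect == "csv")
        utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
    else
        utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("gene", "statistic"))
    CoxRankedList(stats::setNames(as.numeric(df$statistic),
                                  as.character(df$gene)), mode = mode)
}

#' Write an enrichment result table as CSV
#'
#' Columns, exactly: pathway, pval, padj, log2err, ES, NES, size,
#' leadingEdge; the leading edge is serialized as a single
#' semicolon-delimited cell.
#'
#' @param results an [EnrichmentResults-class] or its data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeEnrichmentTable <- function(results, path) {
    tab <- if (is(results, "EnrichmentResults")) enrichTable(results)
           else results
    out <- data.frame(pathway = tab$pathway, pval = tab$pval,
                      padj = tab$padj, log2err = tab$log2err, ES = tab$ES,
                      NES = tab$NES, size = tab$size,
                      leadingEdge = vapply(tab$leadingEdge, paste,
                                           character(1), collapse = ";"))
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    invisible(path)
}

#' Read an enrichment table written by [writeEnrichmentTable()]
#'
#' @param path file path.
#' @param alpha significance level to attach.
#' @return An [EnrichmentResults-class].
#' @export
readEnrichmentTable <- function(path, alpha = 0.15) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    df$leadingEdge <- lapply(strsplit(df$leadingEdge, ";", fixed = TRUE),
                             function(x) x[nzchar(x)])
    new("EnrichmentResults", table = df, alpha = alpha,
        params = list(source = path))
}
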