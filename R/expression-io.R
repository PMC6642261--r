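#' Read a delimited expression table
#'
#' Reads a gene-expression table in either orientation and returns a
#' samples-by-genes numeric matrix with identifiers preserved verbatim.
#' The first column holds row identifiers and the header row holds column
#' identifiers, the convention of TCGA RSEM and GEO series-matrix tables.
#'
#' Missing or non-numeric cells are a hard error naming the offending
#' row/column (biomarker ranking is sensitive to silent imputation) unless
#' `missing = "zero"`, which replaces empty cells with 0. Duplicated
#' identifiers and ragged rows are always errors.
#'
#' @param path path to a delimited text file.
#' @param orientation `"genes-in-rows"` (default; one row per gene,
#'   samples in columns) or `"samples-in-rows"`.
#' @param sep field delimiter; tab by default, `","` for CSV.
#' @param missing `"error"` (default) or `"zero"` (empty cells become 0).
#' @return numeric matrix, samples in rows, genes in columns.
#' @seealso [writeExpressionMatrix()], [DIDataSet()]
#' @export
readExpressionMatrix <- function(path,
                                 orientation = c("genes-in-rows",
                                                 "samples-in-rows"),
                                 sep = "\t",
                                 missing = c("error", "zero")) {
    orientation <- match.arg(orientation)
    missing <- match.arg(missing)
    if (!file.exists(path)) stop("file not found: ", path)
    df <- tryCatch(
        utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "#", quote = "\"",
                          stringsAsFactors = FALSE),
        error = function(e) stop("failed to parse ", path, ": ",
                                 conditionMessage(e), call. = FALSE))
    if (ncol(df) < 2L) stop("table must have an id column and data columns")
    rowIds <- df[[1L]]
    colIds <- colnames(df)[-1L]
    if (anyDuplicated(rowIds))
        stop("duplicate row identifier(s): ",
             paste(unique(rowIds[duplicated(rowIds)]), collapse = ", "))
    if (anyDuplicated(colIds))
        stop("duplicate column identifier(s): ",
             paste(unique(colIds[duplicated(colIds)]), collapse = ", "))
    body <- as.matrix(df[, -1L, drop = FALSE])
    empty <- is.na(body) | !nzchar(trimws(body))
    if (any(empty)) {
        if (missing == "error") {
            i <- which(empty, arr.ind = TRUE)[1L, ]
            stop(sprintf("missing value at row '%s', column '%s'",
                         rowIds[i[1L]], colIds[i[2L]]))
        }
        body[empty] <- "0"
    }
    vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
    if (anyNA(vals)) {
        i <- which(is.na(vals), arr.ind = TRUE)[1L, ]
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                     body[i[1L], i[2L]], rowIds[i[1L]], colIds[i[2L]]))
    }
    if (orientation == "genes-in-rows") {
        dimnames(vals) <- list(rowIds, colIds)
        vals <- t(vals)
    } else {
        dimnames(vals) <- list(rowIds, colIds)
    }
    vals
}

#' Write an expression matrix as delimited text
#'
#' Writes at full double precision so that write-then-read round-trips
#' reproduce the values exactly.
#'
#' @param x samples-by-genes numeric matrix or a [DIDataSet-class].
#' @param path output path.
#' @param orientation orientation of the written file (default
#'   genes-in-rows, the TCGA convention).
#' @param sep field delimiter.
#' @param idHeader header for the identifier column.
#' @export
writeExpressionMatrix <- function(x, path,
                                  orientation = c("genes-in-rows",
                                                  "samples-in-rows"),
                                  sep = "\t", idHeader = "id") {
    orientation <- match.arg(orientation)
    if (is(x, "DIDataSet")) x <- exprValues(x)
    m <- if (orientation == "genes-in-rows") t(x) else x
    lines <- c(
        paste(c(idHeader, colnames(m)), collapse = sep),
        vapply(seq_len(nrow(m)), function(i)
            paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])),
                  collapse = sep), character(1)))
    writeLines(lines, path)
    invisible(path)
}

#' Read per-sample class labels
#'
#' Two-column delimited text (sample id, label), no header by default.
#' Class order is order of first appearance in the file. Every sample of
#' `expr` must be labelled; labels for samples absent from `expr` are
#' dropped with a warning.
#'
#' @param path path to the label file.
#' @param expr samples-by-genes matrix or [DIDataSet-class] whose samples
#'   the labels must cover.
#' @param sep field delimiter.
#' @param header whether the file has a header line.
#' @return named factor in the sample order of `expr`.
#' @export
readLabels <- function(path, expr, sep = "\t", header = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.table(path, sep = sep, header = header,
                            colClasses = "character", check.names = FALSE,
                            quote = "\"", comment.char = "#",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("label file needs two columns: sample id, label")
    ids <- df[[1L]]; labs <- df[[2L]]
    if (anyDuplicated(ids))
        stop("duplicate label for sample(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    samples <- if (is(expr, "DIDataSet")) sampleIds(expr) else rownames(expr)
    unknown <- setdiff(ids, samples)
    if (length(unknown)) {
        warning("ignoring label(s) for unknown sample(s): ",
                paste(unknown, collapse = ", "))
        keep <- ids %in% samples
        ids <- ids[keep]; labs <- labs[keep]
    }
    miss <- setdiff(samples, ids)
    if (length(miss))
        stop("no label for sample(s): ", paste(miss, collapse = ", "))
    out <- factor(labs, levels = unique(labs))[match(samples, ids)]
    names(out) <- samples
    out
}

#' Write per-sample class labels
#'
#' @param labels named factor or character vector (names are sample ids).
#' @param path output path.
#' @param sep field delimiter.
#' @export
writeLabels <- function(labels, path, sep = "\t") {
    if (is.null(names(labels))) stop("labels must be named by sample id")
    writeLines(paste(names(labels), as.character(labels), sep = sep), path)
    invisible(path)
}

#' Read and write gene rankings
#'
#' Rankings are exchanged as three-column TSV (`rank`, `gene_id`,
#' `mean_di`), the format of the full DI-scored gene list the ranking
#' stage emits. Scores are written at full precision; output bytes are
#' deterministic for identical input.
#'
#' @param x a [GeneRanking-class].
#' @param path file path.
#' @return `readRanking` returns a [GeneRanking-class];
#'   `writeRanking` invisibly returns `path`.
#' @export
writeRanking <- function(x, path) {
    stopifnot(is(x, "GeneRanking"))
    validObject(x)
    tab <- x@table
    lines <- c(paste("rank", "gene_id", "mean_di", sep = "\t"),
               if (nrow(tab))
                   paste(tab$rank, tab$gene_id,
                         sprintf("%.17g", tab$mean_di), sep = "\t"))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeRanking
#' @param nIter,seed metadata recorded on the object read back (not stored
#'   in the file).
#' @export
readRanking <- function(path, nIter = NA_integer_, seed = NA_integer_) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (!all(c("rank", "gene_id", "mean_di") %in% colnames(df)))
        stop("ranking file needs columns rank, gene_id, mean_di")
    df <- df[order(df$rank), c("rank", "gene_id", "mean_di")]
    rownames(df) <- NULL
    df$rank <- as.integer(df$rank)
    df$gene_id <- as.character(df$gene_id)
    new("GeneRanking", table = df, nIter = as.integer(nIter),
        seed = as.integer(seed))
}
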