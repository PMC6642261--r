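#' Construct a DIDataSet from a samples-by-genes matrix and labels
#'
#' @param exprs numeric matrix, samples in rows and genes in columns, with
#'   row and column names (the orientation used throughout the user-facing
#'   API; internally genes are stored in rows, following the
#'   `SummarizedExperiment` convention).
#' @param labels class labels, one per sample: a factor or character
#'   vector, either named by sample id or in the row order of `exprs`.
#'   Character input is converted to a factor with levels in order of
#'   first appearance.
#' @return a [DIDataSet-class] object.
#' @examples
#' m <- matrix(abs(rnorm(12)), 4, 3,
#'             dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
#' d <- DIDataSet(m, c("tumor", "tumor", "normal", "normal"))
#' d
#' exprValues(d)[1:2, ]
#' @export
DIDataSet <- function(exprs, labels) {
    if (!is.matrix(exprs) || !is.numeric(exprs))
        stop("'exprs' must be a numeric matrix (samples x genes)")
    if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
        stop("'exprs' needs sample rownames and gene colnames")
    if (!is.null(names(labels))) {
        missing <- setdiff(rownames(exprs), names(labels))
        if (length(missing))
            stop("no label for sample(s): ", paste(missing, collapse = ", "))
        labels <- labels[rownames(exprs)]
    } else if (length(labels) != nrow(exprs)) {
        stop("need one label per sample")
    }
    if (!is.factor(labels))
        labels <- factor(labels, levels = unique(as.character(labels)))
    labels <- droplevels(labels)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = t(exprs)),
        colData = S4Vectors::DataFrame(class = labels,
                                       row.names = rownames(exprs)))
    new("DIDataSet", se)
}

#' @rdname DIDataSet
#' @export
setMethod("exprValues", "DIDataSet", function(x)
    t(SummarizedExperiment::assay(x, "exprs")))

#' @rdname DIDataSet
#' @export
setMethod("geneIds", "DIDataSet", function(x) rownames(x))

#' @rdname DIDataSet
#' @export
setMethod("sampleIds", "DIDataSet", function(x) colnames(x))

#' @rdname DIDataSet
#' @export
setMethod("classLabels", "DIDataSet", function(x) {
    cl <- SummarizedExperiment::colData(x)$class
    names(cl) <- colnames(x)
    cl
})

#' @rdname DIDataSet
#' @export
setMethod("classNames", "DIDataSet", function(x)
    levels(SummarizedExperiment::colData(x)$class))

#' @rdname DIDataSet
#' @export
setMethod("oneHot", "DIDataSet", function(x) {
    cl <- classLabels(x)
    Y <- matrix(0L, length(cl), nlevels(cl),
                dimnames = list(names(cl), levels(cl)))
    Y[cbind(seq_along(cl), as.integer(cl))] <- 1L
    Y
})

setMethod("show", "DIDataSet", function(object) {
    cl <- classLabels(object)
    counts <- table(cl)
    cat(sprintf("DIDataSet: %d samples x %d genes\n",
                ncol(object), nrow(object)))
    cat(sprintf("classes (%d): %s\n", nlevels(cl),
                paste(sprintf("%s (%d)", names(counts), counts),
                      collapse = ", ")))
})
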