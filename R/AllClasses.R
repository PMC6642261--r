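#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Expression data set with class labels
#'
#' `DIDataSet` couples a nonnegative expression matrix (genes in rows, as is
#' conventional for [SummarizedExperiment::SummarizedExperiment-class]
#' containers) with a per-sample class factor stored in `colData(x)$class`.
#' It is the central container consumed by [fitSoftmax()], [rankGenes()] and
#' the evaluation functions.
#'
#' Invariants enforced by the validity method: a single assay named
#' `"exprs"` with finite, nonnegative, non-missing numeric values; at least
#' two genes and two samples; unique gene and sample identifiers; a class
#' factor with at least two levels, every level populated.
#'
#' @seealso [DIDataSet()] for construction from a samples-by-genes matrix.
#' @aliases DIDataSet-class
#' @exportClass DIDataSet
setClass("DIDataSet", contains = "SummarizedExperiment")

setValidity("DIDataSet", function(object) {
    msg <- character()
    if (!identical(SummarizedExperiment::assayNames(object), "exprs"))
        return("assay must be a single matrix named 'exprs'")
    m <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(m))
        msg <- c(msg, "expression values must be numeric")
    else {
        if (anyNA(m))
            msg <- c(msg, "expression values must not contain missing values")
        else if (any(!is.finite(m)))
            msg <- c(msg, "expression values must be finite")
        else if (any(m < 0))
            msg <- c(msg, "expression values must be nonnegative")
    }
    if (nrow(object) < 2L) msg <- c(msg, "need at least 2 genes")
    if (ncol(object) < 2L) msg <- c(msg, "need at least 2 samples")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be present and unique")
    cd <- SummarizedExperiment::colData(object)
    if (!"class" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'class' column")
    else {
        cl <- cd$class
        if (!is.factor(cl)) msg <- c(msg, "'class' must be a factor")
        else {
            if (anyNA(cl)) msg <- c(msg, "every sample needs a class label")
            if (nlevels(cl) < 2L) msg <- c(msg, "need at least 2 classes")
            if (!all(levels(cl) %in% as.character(cl)))
                msg <- c(msg, "every class level must have at least one sample")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Training parameters for the softmax model
#'
#' Created by [trainControl()]. Holds the full-batch gradient-descent
#' hyperparameters: epoch count, learning rate, L2 penalty, initialization
#' scale, gradient-clipping norm, whether a bias is trained, and the
#' per-gene expression transform applied before fitting.
#'
#' @aliases TrainParam-class
#' @exportClass TrainParam
setClass("TrainParam",
    representation(
        epochs = "integer",
        learningRate = "numeric",
        l2 = "numeric",
        initScale = "numeric",
        clipNorm = "numeric",
        useBias = "logical",
        standardize = "character"
    )
)

setValidity("TrainParam", function(object) {
    msg <- character()
    if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
    if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
    if (object@l2 < 0) msg <- c(msg, "l2 must be >= 0")
    if (object@initScale <= 0) msg <- c(msg, "initScale must be > 0")
    if (object@clipNorm <= 0) msg <- c(msg, "clipNorm must be > 0")
    if (!object@standardize %in% c("none", "log2p1", "minmax"))
        msg <- c(msg, "standardize must be one of 'none', 'log2p1', 'minmax'")
    if (length(msg)) msg else TRUE
})

#' Fitted one-layer softmax model
#'
#' Weights are a K x J matrix (one row per class, one column per gene);
#' `bias` has length K when a bias was trained and length 0 otherwise.
#' `meta` records the training configuration actually used (epochs,
#' learning rate, seed, first/final loss, standardization mode) so a fit is
#' reproducible from the object alone.
#'
#' @aliases SoftmaxModel-class
#' @exportClass SoftmaxModel
setClass("SoftmaxModel",
    representation(
        weights = "matrix",
        bias = "numeric",
        meta = "list"
    )
)

setValidity("SoftmaxModel", function(object) {
    msg <- character()
    if (!all(is.finite(object@weights)))
        msg <- c(msg, "weights must be finite")
    if (length(object@bias) && length(object@bias) != nrow(object@weights))
        msg <- c(msg, "bias length must equal the number of classes")
    if (is.null(rownames(object@weights)) || is.null(colnames(object@weights)))
        msg <- c(msg, "weights need class rownames and gene colnames")
    if (length(msg)) msg else TRUE
})

#' Per-gene Discriminative Index scores from one run
#'
#' `scores` is a named nonnegative vector (one entry per gene); `order` the
#' permutation sorting it in descending order, ties broken by ascending
#' gene id; `nPairs` the number of unordered class pairs the index summed
#' over, K(K-1)/2.
#'
#' @aliases DIScores-class
#' @exportClass DIScores
setClass("DIScores",
    representation(
        scores = "numeric",
        order = "integer",
        nPairs = "integer",
        classes = "character"
    )
)

setValidity("DIScores", function(object) {
    msg <- character()
    s <- object@scores
    if (is.null(names(s))) msg <- c(msg, "scores must be named by gene id")
    if (any(s < 0)) msg <- c(msg, "DI scores must be nonnegative")
    o <- object@order
    if (length(o) != length(s) || !setequal(o, seq_along(s)))
        msg <- c(msg, "'order' must be a permutation of the gene indices")
    else if (is.unsorted(rev(s[o])))
        msg <- c(msg, "scores in sorted order must be non-increasing")
    if (length(msg)) msg else TRUE
})

#' Averaged gene ranking
#'
#' The result of [rankGenes()]: a table with columns `rank` (1..J, no
#' gaps), `gene_id` and `mean_di` (non-increasing), plus the number of
#' averaged runs and the base seed used.
#'
#' @aliases GeneRanking-class
#' @exportClass GeneRanking
setClass("GeneRanking",
    representation(
        table = "data.frame",
        nIter = "integer",
        seed = "integer"
    )
)

setValidity("GeneRanking", function(object) {
    tab <- object@table
    msg <- character()
    need <- c("rank", "gene_id", "mean_di")
    if (!identical(colnames(tab), need))
        return(sprintf("ranking table must have columns %s",
                       paste(need, collapse = ", ")))
    if (nrow(tab)) {
        if (!identical(as.integer(tab$rank), seq_len(nrow(tab))))
            msg <- c(msg, "ranks must be 1..J with no gaps")
        if (anyDuplicated(tab$gene_id))
            msg <- c(msg, "gene ids must be unique")
        if (is.unsorted(rev(tab$mean_di)))
            msg <- c(msg, "mean_di must be non-increasing with rank")
        if (any(tab$mean_di < 0))
            msg <- c(msg, "mean_di must be nonnegative")
    }
    if (length(msg)) msg else TRUE
})

#' Planted-signal ground truth from the synthetic generator
#'
#' Which genes carry a class-conditional mean shift, and the expected
#' per-class means (expression units) for each of them.
#'
#' @aliases PlantedTruth-class
#' @exportClass PlantedTruth
setClass("PlantedTruth",
    representation(
        geneIds = "character",
        classMeans = "matrix"
    )
)

setValidity("PlantedTruth", function(object) {
    if (length(object@geneIds) != nrow(object@classMeans))
        "one row of classMeans per planted gene" else TRUE
})
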