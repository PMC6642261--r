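#' @rdname DIDataSet
#' @param object,x a `DIDataSet` (or other object, see methods)
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname DIDataSet
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname DIDataSet
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname DIDataSet
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname DIDataSet
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname DIDataSet
#' @export
setGeneric("oneHot", function(x) standardGeneric("oneHot"))

#' @rdname fitSoftmax
#' @export
setGeneric("fitSoftmax", function(x, param = trainControl(), seed = 1L)
    standardGeneric("fitSoftmax"))

#' @rdname predictProba
#' @export
setGeneric("predictProba", function(object, newdata)
    standardGeneric("predictProba"))

#' @rdname classMeans
#' @export
setGeneric("classMeans", function(x, standardize = "none")
    standardGeneric("classMeans"))

#' @rdname runDIOnce
#' @export
setGeneric("runDIOnce", function(x, param = trainControl(), seed = 1L)
    standardGeneric("runDIOnce"))

#' @rdname rankGenes
#' @export
setGeneric("rankGenes", function(x, param = trainControl(), nIter = 10000L,
                                 seed = 1L, resplitFraction = NULL)
    standardGeneric("rankGenes"))

#' @rdname GeneRanking-accessors
#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))

#' @rdname GeneRanking-accessors
#' @export
setGeneric("topGenes", function(x, c) standardGeneric("topGenes"))

#' @rdname DIScores-accessors
#' @export
setGeneric("diScores", function(x) standardGeneric("diScores"))

#' @rdname DIScores-accessors
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname simulateExpression
#' @export
setGeneric("plantedIds", function(x) standardGeneric("plantedIds"))
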