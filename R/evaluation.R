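#' Class-ratio-preserving sample split
#'
#' Randomly partitions samples into the requested fractions while
#' maintaining each class's proportions, the way cohorts are divided into
#' feature-selection/validation halves or train/validation/test sets.
#' Within each class, every partition except a designated remainder
#' partition receives `round(fraction * n_class)` samples (half rounded
#' up); the remainder partition absorbs what is left, so partitions are
#' disjoint and exhaustive. With three fractions 0.64/0.16/0.20 on a
#' 1,257 + 3,256 two-class cohort this yields 2,888/723/902.
#'
#' @param labels named factor of class labels (names are sample ids), or a
#'   [DIDataSet-class].
#' @param fractions numeric vector of partition proportions, each in
#'   (0, 1), summing to 1.
#' @param seed integer seed; the same seed reproduces the assignment
#'   exactly.
#' @param remainder index of the partition absorbing per-class rounding
#'   leftovers; defaults to 2 (the validation partition in a
#'   train/validation/test split).
#' @return named list of character vectors of sample ids, one per
#'   fraction.
#' @export
stratifiedSplit <- function(labels, fractions, seed = 1L, remainder = 2L) {
    if (is(labels, "DIDataSet")) labels <- classLabels(labels)
    if (is.null(names(labels))) stop("labels must be named by sample id")
    labels <- droplevels(as.factor(labels))
    P <- length(fractions)
    if (P < 2L) stop("need at least 2 fractions")
    if (any(fractions <= 0 | fractions >= 1))
        stop("each fraction must be in (0, 1)")
    if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
    remainder <- as.integer(remainder)
    if (remainder < 1L || remainder > P)
        stop("'remainder' must index one of the fractions")
    small <- table(labels) < P
    if (any(small))
        stop("class(es) smaller than the number of partitions: ",
             paste(names(which(small)), collapse = ", "))
    parts <- rep(list(character(0)), P)
    set.seed(seed)
    for (k in levels(labels)) {
        ids <- sample(names(labels)[labels == k])
        n <- length(ids)
        sizes <- floor(fractions * n + 0.5)          # round half up
        sizes[remainder] <- 0L
        sizes[remainder] <- n - sum(sizes)
        if (sizes[remainder] < 0L)
            stop("rounding left no samples for the remainder partition in class ", k)
        stops <- cumsum(sizes)
        starts <- c(0L, stops[-P]) + 1L
        for (p in seq_len(P))
            if (sizes[p] > 0L)
                parts[[p]] <- c(parts[[p]], ids[starts[p]:stops[p]])
    }
    names(parts) <- if (!is.null(names(fractions))) names(fractions)
                    else paste0("partition", seq_len(P))
    parts
}

#' Restrict a data set to a gene list
#'
#' @param x a [DIDataSet-class] or samples-by-genes matrix.
#' @param genes character vector of gene ids to keep, in the desired
#'   column order. Unknown ids are an error.
#' @return object of the same type with columns restricted to `genes`.
#' @export
reduceFeatures <- function(x, genes) {
    if (!length(genes)) stop("'genes' must not be empty")
    have <- if (is(x, "DIDataSet")) geneIds(x) else colnames(x)
    unknown <- setdiff(genes, have)
    if (length(unknown))
        stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
    if (is(x, "DIDataSet")) x[genes, ] else x[, genes, drop = FALSE]
}

## labels as 0-based integers for xgboost
xgbLabels <- function(cl) as.integer(cl) - 1L

fitClassifier <- function(train, classifier, seed, nrounds, maxDepth, eta,
                          param) {
    cl <- classLabels(train)
    K <- nlevels(cl)
    if (classifier == "xgboost") {
        params <- list(max_depth = maxDepth, eta = eta, nthread = 1,
                       seed = seed, tree_method = "exact")
        if (K == 2L) {
            params$objective <- "binary:logistic"
        } else {
            params$objective <- "multi:softprob"
            params$num_class <- K
        }
        dm <- xgboost::xgb.DMatrix(exprValues(train),
                                   label = xgbLabels(cl), nthread = 1)
        booster <- xgboost::xgb.train(params = params, data = dm,
                                      nrounds = nrounds, verbose = 0)
        list(kind = "xgboost", fit = booster, levels = levels(cl))
    } else {
        list(kind = "softmax", fit = fitSoftmax(train, param, seed),
             levels = levels(cl))
    }
}

predictClasses <- function(model, newX) {
    if (model$kind == "xgboost") {
        p <- predict(model$fit, xgboost::xgb.DMatrix(newX, nthread = 1))
        K <- length(model$levels)
        idx <- if (K == 2L) ifelse(p > 0.5, 2L, 1L)
               else max.col(if (is.matrix(p)) p
                            else matrix(p, ncol = K, byrow = TRUE))
        factor(model$levels[idx], levels = model$levels)
    } else {
        P <- predictProba(model$fit,
                          standardizeExpression(newX,
                                                model$fit@meta$standardize))
        factor(model$levels[max.col(P)], levels = model$levels)
    }
}

#' Train a classifier and score it on held-out samples
#'
#' Fits either a gradient-boosted tree ensemble (default, via xgboost,
#' single-threaded and seeded for reproducibility) or the package's
#' one-layer softmax model on the training set, and reports plain accuracy
#' (fraction of test samples correctly classified) plus the confusion
#' table. Note: plain accuracy, not balanced accuracy — with the strong
#' class imbalance typical of tumor/normal cohorts, the majority class
#' dominates this number.
#'
#' @param train,test [DIDataSet-class] objects sharing the same gene set
#'   and class levels.
#' @param classifier `"xgboost"` or `"softmax"`.
#' @param seed integer seed for the classifier.
#' @param nrounds,maxDepth,eta boosting rounds, tree depth and shrinkage
#'   for the xgboost family.
#' @param param [TrainParam-class] for the softmax family.
#' @return list with `accuracy`, `confusion` (observed x predicted counts)
#'   and `n` (number of test samples).
#' @export
trainAndScore <- function(train, test, classifier = c("xgboost", "softmax"),
                          seed = 1L, nrounds = 50L, maxDepth = 3L,
                          eta = 0.3, param = trainControl()) {
    classifier <- match.arg(classifier)
    if (!identical(sort(geneIds(train)), sort(geneIds(test))))
        stop("train and test must share the same gene set")
    test <- test[geneIds(train), ]
    if (!identical(classNames(train), classNames(test)))
        stop("train and test must share the same class levels")
    model <- fitClassifier(train, classifier, seed, nrounds, maxDepth, eta,
                           param)
    pred <- predictClasses(model, exprValues(test))
    obs <- classLabels(test)
    conf <- table(observed = obs, predicted = pred)
    list(accuracy = mean(pred == obs), confusion = conf, n = length(obs))
}

#' Accuracy as a function of the number of top-ranked genes
#'
#' For each requested k, restricts both data sets to the top-k genes of
#' the ranking and runs [trainAndScore()]; the resulting curve shows how
#' quickly classification accuracy saturates as lower-ranked genes are
#' added.
#'
#' @param ranking a [GeneRanking-class].
#' @param train,val [DIDataSet-class] objects.
#' @param ks integer vector of feature counts, each between 1 and J.
#' @param ... passed to [trainAndScore()].
#' @return data.frame with columns `k` and `accuracy`.
#' @export
topkAccuracyCurve <- function(ranking, train, val, ks, ...) {
    J <- nrow(rankingTable(ranking))
    ks <- as.integer(ks)
    if (any(is.na(ks) | ks < 1L | ks > J))
        stop(sprintf("each k must be between 1 and %d", J))
    acc <- vapply(ks, function(k) {
        genes <- topGenes(ranking, k)
        trainAndScore(reduceFeatures(train, genes),
                      reduceFeatures(val, genes), ...)$accuracy
    }, numeric(1))
    data.frame(k = ks, accuracy = acc)
}

#' Leave-one-out cross-validated accuracy
#'
#' Performs exactly N fits, each trained on N - 1 samples and scored on
#' the held-out one; accuracy is the fraction of held-out samples
#' predicted correctly (so it is quantized to multiples of 1/N).
#'
#' @param x a [DIDataSet-class].
#' @param genes optional gene list to restrict to first.
#' @param classifier,seed,nrounds,maxDepth,eta,param classifier family and
#'   hyperparameters, as in [trainAndScore()]; every fold retrains with
#'   identical settings.
#' @return list with `accuracy`, `nFits` (= N), `predicted` and
#'   `observed` factors, and the `confusion` table.
#' @export
loocvAccuracy <- function(x, genes = NULL,
                          classifier = c("xgboost", "softmax"), seed = 1L,
                          nrounds = 50L, maxDepth = 3L, eta = 0.3,
                          param = trainControl()) {
    if (!is.null(genes)) x <- reduceFeatures(x, genes)
    cl <- classLabels(x)
    if (length(cl) < 3L) stop("need at least 3 samples for LOOCV")
    if (any(table(cl) < 2L))
        stop("every class needs at least 2 samples (a singleton class ",
             "would vanish from its training fold)")
    N <- length(cl)
    classifier <- match.arg(classifier)
    preds <- character(N)
    nFits <- 0L
    for (i in seq_len(N)) {
        model <- fitClassifier(x[, -i], classifier, seed, nrounds, maxDepth,
                               eta, param)
        nFits <- nFits + 1L
        heldOut <- exprValues(x)[i, , drop = FALSE]
        preds[i] <- as.character(predictClasses(model, heldOut))
    }
    predicted <- factor(preds, levels = levels(cl))
    names(predicted) <- names(cl)
    list(accuracy = mean(predicted == cl), nFits = nFits,
         predicted = predicted, observed = cl,
         confusion = table(observed = cl, predicted = predicted))
}

## round half away from zero at one decimal, on an exactly-computed
## tenths scale so printed percentages like 18.95 -> 19.0 do not fall
## victim to binary floating point
roundPercentTenths <- function(numer, denom) {
    floor(1000 * numer / denom + 0.5) / 10
}

#' Overlap between two gene rankings as a function of depth
#'
#' For each depth d, the percentage of genes shared by the two top-d
#' lists: `100 * |top_d(a) intersect top_d(b)| / d`, reported to one
#' decimal, rounded half away from zero (45 shared of 500 -> 9.0; 379 of
#' 2,000 -> 19.0). Symmetric in its arguments. Either argument may be a
#' ranking imported from an external tool (e.g. a differential-expression
#' gene list read with [readRanking()]); only the gene order is used.
#'
#' @param a,b [GeneRanking-class] objects, or character vectors of gene
#'   ids already in rank order.
#' @param depths integer depths, each between 1 and the shorter list's
#'   length.
#' @return data.frame with columns `depth` and `overlap` (percent).
#' @export
rankingOverlap <- function(a, b, depths) {
    ga <- if (is(a, "GeneRanking")) rankingTable(a)$gene_id else as.character(a)
    gb <- if (is(b, "GeneRanking")) rankingTable(b)$gene_id else as.character(b)
    depths <- as.integer(depths)
    if (any(is.na(depths) | depths < 1L))
        stop("each depth must be a positive integer")
    if (any(depths > min(length(ga), length(gb))))
        stop("depth exceeds ranking length")
    ov <- vapply(depths, function(d)
        roundPercentTenths(length(intersect(ga[seq_len(d)],
                                            gb[seq_len(d)])), d),
        numeric(1))
    data.frame(depth = depths, overlap = ov)
}

#' Area under the ROC curve for a two-class score
#'
#' Thin wrapper around [pROC::auc()] for scoring a continuous predictor
#' (e.g. the probability of the positive class) against binary labels.
#'
#' @param scores numeric vector.
#' @param labels two-level factor (second level = positive).
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, labels) {
    labels <- droplevels(as.factor(labels))
    if (nlevels(labels) != 2L) stop("AUC needs exactly 2 classes")
    as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                   levels = levels(labels),
                                   direction = "<", quiet = TRUE)))
}

#' Pan-cancer cohort sample counts
#'
#' The per-cohort tumor/normal sample counts of the 12-cancer TCGA
#' pan-cancer compendium the method was originally applied to, shipped as
#' plain text in `inst/extdata/pancancer_cohorts.tsv`. Useful for
#' bookkeeping checks and for configuring the synthetic generator to
#' realistic cohort sizes and imbalance.
#'
#' @return data.frame with columns `type_id`, `name`, `cancer`, `normal`,
#'   `total`.
#' @examples
#' cc <- pancancerCohorts()
#' colSums(cc[, c("cancer", "normal", "total")])
#' @export
pancancerCohorts <- function() {
    path <- system.file("extdata", "pancancer_cohorts.tsv",
                        package = "DIselect", mustWork = TRUE)
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
}
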