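#' Training parameter constructor
#'
#' Full-batch gradient descent defaults: 100 epochs, learning rate 0.01
#' with the global gradient norm clipped at 1, no L2 penalty, bias on,
#' zero-mean uniform initialization scaled by `initScale / sqrt(J)`. The
#' `standardize` transform is applied per gene before fitting (and, in the
#' ranking pipeline, before computing class means): `"none"` (default;
#' inputs are assumed to be normalized expression already), `"log2p1"`
#' (log2(x + 1)) or `"minmax"` (per-gene rescaling to [0, 1]).
#'
#' @param epochs number of full-batch gradient steps.
#' @param learningRate step size.
#' @param l2 L2 penalty on the weights (not the bias).
#' @param initScale multiplier on the 1/sqrt(J) initialization range.
#' @param clipNorm maximum global gradient norm per step.
#' @param useBias whether to train a per-class intercept. The bias never
#'   enters the Discriminative Index, which is defined per gene.
#' @param standardize per-gene transform, see Details.
#' @return a [TrainParam-class] object.
#' @export
trainControl <- function(epochs = 100L, learningRate = 0.01, l2 = 0,
                         initScale = 1, clipNorm = 1, useBias = TRUE,
                         standardize = c("none", "log2p1", "minmax")) {
    new("TrainParam", epochs = as.integer(epochs),
        learningRate = learningRate, l2 = l2, initScale = initScale,
        clipNorm = clipNorm, useBias = useBias,
        standardize = match.arg(standardize))
}

setMethod("show", "TrainParam", function(object) {
    cat(sprintf(paste0("TrainParam: %d epochs, lr %g (clip %g), l2 %g, ",
                       "initScale %g, bias %s, standardize '%s'\n"),
                object@epochs, object@learningRate, object@clipNorm,
                object@l2, object@initScale,
                if (object@useBias) "on" else "off", object@standardize))
})

## Per-gene expression transform shared by fitting and class means.
standardizeExpression <- function(m, mode) {
    switch(mode,
        none = m,
        log2p1 = log2(m + 1),
        minmax = {
            rng <- apply(m, 2L, range)
            span <- rng[2L, ] - rng[1L, ]
            span[span == 0] <- 1        # constant genes map to 0
            sweep(sweep(m, 2L, rng[1L, ], "-"), 2L, span, "/")
        },
        stop("unknown standardize mode: ", mode))
}

## Deterministic 31-bit hash of a gene id, used to key each gene's
## initialization stream so that permuting gene columns permutes the
## initial weights with them (exact permutation equivariance of the
## pipeline) and adding/removing samples leaves the init unchanged.
geneHash <- function(ids) {
    vapply(ids, function(s) {
        v <- utf8ToInt(s)
        h <- 0
        for (x in v) h <- (h * 131 + x) %% 2147483647
        h
    }, numeric(1), USE.NAMES = FALSE)
}

## K x J initial weight matrix: each gene's column drawn from its own
## seeded stream, zero-mean uniform scaled by initScale / sqrt(J).
initWeights <- function(classes, genes, initScale, seed) {
    K <- length(classes); J <- length(genes)
    h <- geneHash(genes)
    W <- matrix(0, K, J, dimnames = list(classes, genes))
    half <- initScale / sqrt(J)
    s <- abs(seed) %% 2147483647
    for (j in seq_len(J)) {
        set.seed((h[j] * 69069 + s * 40503) %% 2147483646 + 1)
        W[, j] <- stats::runif(K, -half, half)
    }
    W
}

## row-wise numerically stable softmax
softmaxRows <- function(S) {
    S <- S - apply(S, 1L, max)
    E <- exp(S)
    E / rowSums(E)
}

#' Fit a one-layer softmax regression
#'
#' Minimizes the multinomial cross-entropy of normalized-exponential class
#' probabilities, `P(class k | x) = exp(theta_k' x) / sum_l exp(theta_l' x)`,
#' by full-batch gradient descent with gradient-norm clipping. Training is
#' reproducible given `seed`; the first- and final-epoch losses are kept in
#' `meta` so the fit's progress can be audited.
#'
#' @param x a [DIDataSet-class].
#' @param param a [TrainParam-class] from [trainControl()].
#' @param seed integer seed controlling the random initialization.
#' @return a [SoftmaxModel-class].
#' @examples
#' sim <- simulateExpression(nPerClass = c(tumor = 20, normal = 20),
#'                           nGenes = 30, plantedGenes = 1:2, seed = 1)
#' fit <- fitSoftmax(sim$dataset, trainControl(epochs = 50), seed = 1)
#' fit
#' @rdname fitSoftmax
#' @export
setMethod("fitSoftmax", "DIDataSet", function(x, param = trainControl(),
                                              seed = 1L) {
    validObject(param)
    X <- standardizeExpression(exprValues(x), param@standardize)
    Y <- oneHot(x)
    fitSoftmaxMatrix(X, Y, param, seed)
})

## workhorse on plain matrices (X: N x J, Y: N x K one-hot)
fitSoftmaxMatrix <- function(X, Y, param, seed) {
    N <- nrow(X); J <- ncol(X); K <- ncol(Y)
    if (K < 2L) stop("need at least 2 classes")
    if (any(colSums(Y) == 0))
        stop("class with zero samples: ",
             paste(colnames(Y)[colSums(Y) == 0], collapse = ", "))
    W <- initWeights(colnames(Y), colnames(X), param@initScale, seed)
    b <- numeric(K)
    lr <- param@learningRate
    lossAt <- function(W, b) {
        S <- X %*% t(W)
        if (param@useBias) S <- sweep(S, 2L, b, "+")
        P <- softmaxRows(S)
        -mean(log(pmax(rowSums(P * Y), .Machine$double.xmin))) +
            0.5 * param@l2 * sum(W^2)
    }
    lossFirst <- NA_real_
    for (e in seq_len(param@epochs)) {
        S <- X %*% t(W)
        if (param@useBias) S <- sweep(S, 2L, b, "+")
        P <- softmaxRows(S)
        loss <- -mean(log(pmax(rowSums(P * Y), .Machine$double.xmin))) +
            0.5 * param@l2 * sum(W^2)
        if (!is.finite(loss))
            stop(sprintf(
                "training diverged (non-finite loss at epoch %d); reduce learning rate %g",
                e, lr))
        if (e == 1L) lossFirst <- loss
        D <- P - Y
        GW <- crossprod(D, X) / N + param@l2 * W
        Gb <- colMeans(D)
        gn <- sqrt(sum(GW^2) + if (param@useBias) sum(Gb^2) else 0)
        if (gn > param@clipNorm) {
            GW <- GW * (param@clipNorm / gn)
            Gb <- Gb * (param@clipNorm / gn)
        }
        W <- W - lr * GW
        if (param@useBias) b <- b - lr * Gb
    }
    lossFinal <- lossAt(W, b)
    if (!is.finite(lossFinal))
        stop(sprintf("training diverged; reduce learning rate %g", lr))
    new("SoftmaxModel", weights = W,
        bias = if (param@useBias) b else numeric(0),
        meta = list(epochs = param@epochs, learningRate = lr,
                    l2 = param@l2, initScale = param@initScale,
                    clipNorm = param@clipNorm,
                    standardize = param@standardize, seed = as.integer(seed),
                    lossFirst = lossFirst, lossFinal = lossFinal))
}

#' Class probabilities from a fitted softmax model
#'
#' Normalized exponentials of the linear scores, computed with
#' max-subtraction so arbitrarily large scores (|theta' x| up to 1e4 and
#' beyond) do not overflow. Rows sum to 1 to within 1e-12.
#'
#' @param object a [SoftmaxModel-class].
#' @param newdata numeric vector of length J, or an N x J matrix, or a
#'   [DIDataSet-class] (its `standardize` transform from training is
#'   re-applied).
#' @return K-vector of probabilities, or an N x K matrix for matrix input.
#' @rdname predictProba
#' @export
setMethod("predictProba", "SoftmaxModel", function(object, newdata) {
    vec <- is.null(dim(newdata)) && !is(newdata, "DIDataSet")
    if (is(newdata, "DIDataSet"))
        newdata <- standardizeExpression(exprValues(newdata),
                                         object@meta$standardize)
    X <- if (vec) matrix(newdata, nrow = 1L) else as.matrix(newdata)
    if (ncol(X) != ncol(object@weights))
        stop(sprintf("expected %d features, got %d",
                     ncol(object@weights), ncol(X)))
    if (any(!is.finite(X))) stop("'newdata' must be finite")
    S <- X %*% t(object@weights)
    if (length(object@bias)) S <- sweep(S, 2L, object@bias, "+")
    P <- softmaxRows(S)
    colnames(P) <- rownames(object@weights)
    if (vec) P[1L, ] else P
})

setMethod("show", "SoftmaxModel", function(object) {
    cat(sprintf("SoftmaxModel: %d classes x %d genes, bias %s\n",
                nrow(object@weights), ncol(object@weights),
                if (length(object@bias)) "on" else "off"))
    cat(sprintf("  trained %d epochs (lr %g, seed %d); loss %.5f -> %.5f\n",
                object@meta$epochs, object@meta$learningRate,
                object@meta$seed, object@meta$lossFirst,
                object@meta$lossFinal))
})
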