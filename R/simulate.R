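#' Simulate an expression cohort with planted discriminative genes
#'
#' Generates a samples-by-genes matrix emulating the structure of
#' normalized bulk RNA-seq cohorts: right-skewed nonnegative values,
#' thousands of genes, imbalanced classes (default 180 "cancer" vs 20
#' "normal", the ~90/10 imbalance typical of tumor/normal compendia), and
#' a small planted subset of genes whose class-conditional means differ by
#' an additive shift in expression units. Everything else is
#' class-independent noise, so the planted set is the ground truth a
#' ranking method should recover.
#'
#' Per-gene baseline means are drawn once from a lognormal with log-mean
#' `baseMeanLog` and log-sd `baseSdLog` (default: median ~100, the scale
#' of RSEM-normalized counts). Sample values are then drawn around the
#' class mean from the chosen distribution, parameterized so the expected
#' value equals the class mean exactly: `"lognormal"` (default; within-gene
#' log-sd `noiseSdLog`), `"gamma"` or `"nbinom"` (dispersion
#' `dispersion`). The default planted shift of +500 on the first class is
#' a strong effect (~9 within-class standard deviations at the default
#' noise level).
#'
#' @param nPerClass named integer vector of per-class sample counts
#'   (names become the class labels; defaults `c(cancer = 180,
#'   normal = 20)`).
#' @param nGenes number of genes J.
#' @param plantedGenes integer indices (in 1..J) of planted genes.
#' @param plantedShift either a single number — an additive mean shift in
#'   expression units applied to the first class for every planted gene —
#'   or a length(plantedGenes) x K matrix of per-class shifts.
#' @param baseMeanLog,baseSdLog log-mean and log-sd of per-gene baseline
#'   means across genes.
#' @param noiseSdLog within-gene lognormal noise log-sd.
#' @param dispersion dispersion for the gamma / negative-binomial modes
#'   (variance = mean^2 * dispersion^2, and + mean for nbinom).
#' @param distribution `"lognormal"`, `"gamma"` or `"nbinom"`.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return list with `dataset` (a [DIDataSet-class]) and `truth` (a
#'   [PlantedTruth-class] holding the planted gene ids and their expected
#'   per-class means).
#' @examples
#' sim <- simulateExpression(nPerClass = c(cancer = 30, normal = 10),
#'                           nGenes = 100, plantedGenes = 1:5, seed = 42)
#' sim$dataset
#' plantedIds(sim$truth)
#' @export
simulateExpression <- function(nPerClass = c(cancer = 180, normal = 20),
                               nGenes = 1000L,
                               plantedGenes = 1:10,
                               plantedShift = 500,
                               baseMeanLog = log(100), baseSdLog = 0.5,
                               noiseSdLog = 0.5, dispersion = 0.25,
                               distribution = c("lognormal", "gamma",
                                                "nbinom"),
                               seed = 1L) {
    distribution <- match.arg(distribution)
    classNamesV <- names(nPerClass)
    nPerClass <- as.integer(nPerClass)
    if (any(is.na(nPerClass) | nPerClass < 1L))
        stop("each class needs at least 1 sample")
    K <- length(nPerClass)
    if (K < 2L) stop("need at least 2 classes")
    if (is.null(classNamesV))
        classNamesV <- if (K == 2L) c("cancer", "normal")
                       else paste0("class", seq_len(K))
    names(nPerClass) <- classNamesV
    J <- as.integer(nGenes)
    if (J < 2L) stop("need at least 2 genes")
    plantedGenes <- as.integer(plantedGenes)
    if (any(plantedGenes < 1L | plantedGenes > J))
        stop("planted gene indices must lie in 1..nGenes")
    p <- length(plantedGenes)
    if (is.matrix(plantedShift)) {
        if (!identical(dim(plantedShift), c(p, K)))
            stop(sprintf("'plantedShift' matrix must be %d x %d", p, K))
        shifts <- plantedShift
    } else {
        shifts <- matrix(0, p, K)
        if (p) shifts[, 1L] <- plantedShift
    }
    if (baseSdLog <= 0 || noiseSdLog <= 0 || dispersion <= 0)
        stop("scale parameters must be positive")

    geneIdsV <- sprintf("gene%0*d", nchar(J), seq_len(J))
    N <- sum(nPerClass)
    sampleIdsV <- sprintf("sample%0*d", nchar(N), seq_len(N))
    labels <- factor(rep(names(nPerClass), nPerClass),
                     levels = names(nPerClass))
    names(labels) <- sampleIdsV

    set.seed(seed)
    base <- stats::rlnorm(J, baseMeanLog, baseSdLog)
    mu <- matrix(rep(base, each = K), K, J)    # K x J class means
    if (p)
        for (q in seq_len(p))
            mu[, plantedGenes[q]] <- pmax(base[plantedGenes[q]] +
                                          shifts[q, ], 1e-8)
    cls <- as.integer(labels)
    X <- matrix(0, N, J, dimnames = list(sampleIdsV, geneIdsV))
    for (j in seq_len(J)) {
        m <- mu[cls, j]
        X[, j] <- switch(distribution,
            lognormal = stats::rlnorm(N, log(m) - noiseSdLog^2 / 2,
                                      noiseSdLog),
            gamma = stats::rgamma(N, shape = 1 / dispersion^2,
                                  rate = 1 / (dispersion^2 * m)),
            nbinom = stats::rnbinom(N, mu = m, size = 1 / dispersion^2))
    }
    cm <- t(mu[, plantedGenes, drop = FALSE])
    dimnames(cm) <- list(geneIdsV[plantedGenes], names(nPerClass))
    truth <- new("PlantedTruth", geneIds = geneIdsV[plantedGenes],
                 classMeans = cm)
    list(dataset = DIDataSet(X, labels), truth = truth)
}

#' @rdname simulateExpression
#' @param x a [PlantedTruth-class]
#' @export
setMethod("plantedIds", "PlantedTruth", function(x) x@geneIds)

setMethod("show", "PlantedTruth", function(object) {
    cat(sprintf("PlantedTruth: %d planted gene(s) across %d classes\n",
                length(object@geneIds), ncol(object@classMeans)))
})

#' Fraction of planted genes recovered in the top of a ranking
#'
#' `|top_c(ranking) intersect planted| / |planted|` — the package's main
#' correctness surrogate: a ranking that works should place strongly
#' planted genes at the top.
#'
#' @param ranking a [GeneRanking-class].
#' @param truth a [PlantedTruth-class] (or character vector of planted
#'   gene ids).
#' @param c ranking depth to inspect.
#' @return fraction in [0, 1].
#' @export
recoveryRate <- function(ranking, truth, c) {
    planted <- if (is(truth, "PlantedTruth")) plantedIds(truth)
               else as.character(truth)
    if (!length(planted)) stop("empty planted gene set")
    top <- topGenes(ranking, c)
    length(intersect(top, planted)) / length(planted)
}
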