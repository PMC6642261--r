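makeLabels <- function(counts) {
    lab <- factor(rep(names(counts), counts), levels = names(counts))
    names(lab) <- paste0("s", seq_along(lab))
    lab
}

test_that("the 64/16/20 split of a 1257+3256 cohort gives 2888/723/902", {
    lab <- makeLabels(c(pos = 1257, neg = 3256))
    parts <- stratifiedSplit(lab, c(0.64, 0.16, 0.20), seed = 7)
    expect_identical(unname(lengths(parts)), c(2888L, 723L, 902L))
    # disjoint and exhaustive
    all <- unlist(parts, use.names = FALSE)
    expect_identical(sort(all), sort(names(lab)))
    expect_identical(anyDuplicated(all), 0L)
})

test_that("splits preserve class ratios within rounding", {
    set.seed(123)
    for (rep in 1:10) {
        counts <- c(a = sample(20:200, 1), b = sample(20:200, 1),
                    c = sample(20:200, 1))
        fr <- c(0.61, 0.17, 0.22)
        lab <- makeLabels(counts)
        parts <- stratifiedSplit(lab, fr, seed = rep)
        for (k in names(counts)) {
            nk <- counts[[k]]
            got <- vapply(parts, function(p)
                sum(lab[p] == k) / nk, numeric(1))
            expect_true(all(abs(got - fr) < 1 / nk))
        }
    }
})

test_that("exactly divisible splits are exact and seed-reproducible", {
    lab <- makeLabels(c(a = 6, b = 4))
    p1 <- stratifiedSplit(lab, c(0.5, 0.5), seed = 3)
    expect_identical(unname(lengths(p1)), c(5L, 5L))
    expect_identical(vapply(p1, function(p) sum(lab[p] == "a"), 0L),
                     c(partition1 = 3L, partition2 = 3L))
    expect_identical(p1, stratifiedSplit(lab, c(0.5, 0.5), seed = 3))
    expect_false(identical(p1, stratifiedSplit(lab, c(0.5, 0.5), seed = 4)))
})

test_that("degenerate split requests are refused", {
    lab <- makeLabels(c(a = 2, b = 9))
    expect_error(stratifiedSplit(lab, c(0.4, 0.3, 0.3), seed = 1),
                 "smaller than the number of partitions")
    expect_error(stratifiedSplit(makeLabels(c(a = 5, b = 5)), c(0.6, 0.5)),
                 "sum to 1")
})

test_that("feature reduction slices columns and validates ids", {
    d <- separableDataset(nPerClass = 4, j = 5, seed = 21)
    expect_equal(exprValues(reduceFeatures(d, geneIds(d))), exprValues(d))
    r <- reduceFeatures(d, c("g4", "g2"))
    expect_identical(geneIds(r), c("g4", "g2"))
    expect_equal(exprValues(r), exprValues(d)[, c("g4", "g2")])
    expect_error(reduceFeatures(d, character(0)), "empty")
    expect_error(reduceFeatures(d, c("g1", "nope")), "nope")
})

test_that("both classifier families nail linearly separable data", {
    d <- separableDataset(nPerClass = 10, j = 3, seed = 22)
    for (clf in c("xgboost", "softmax")) {
        res <- trainAndScore(d, d, classifier = clf, seed = 1)
        expect_equal(res$accuracy, 1.0)
        expect_identical(sum(res$confusion), res$n)
    }
})

test_that("label-independent features score near the majority fraction", {
    set.seed(30)
    n <- 60
    m <- matrix(abs(rnorm(n * 10, 5, 1)), n, 10,
                dimnames = list(paste0("s", 1:n), paste0("g", 1:10)))
    lab <- rep(c("maj", "min"), c(42, 18))     # majority fraction 0.7
    train <- DIDataSet(m[seq(1, n, 2), ], lab[seq(1, n, 2)])
    test <- DIDataSet(m[seq(2, n, 2), ], lab[seq(2, n, 2)])
    accs <- vapply(1:5, function(s)
        trainAndScore(train, test, seed = s)$accuracy, numeric(1))
    expect_true(abs(mean(accs) - 0.7) < 0.2)
})

test_that("top-k curve rises to the planted set then plateaus", {
    sim <- simulateExpression(nPerClass = c(cancer = 40, normal = 40),
                              nGenes = 30, plantedGenes = 1:5, seed = 33)
    d <- sim$dataset
    parts <- stratifiedSplit(d, c(0.5, 0.5), seed = 1)
    train <- d[, parts[[1]]]; val <- d[, parts[[2]]]
    rk <- rankGenes(d, nIter = 5, seed = 2)
    curve <- topkAccuracyCurve(rk, train, val, ks = c(1, 5, 15, 30),
                               seed = 1)
    expect_true(all(curve$accuracy >= 0 & curve$accuracy <= 1))
    a <- setNames(curve$accuracy, curve$k)
    expect_gte(a[["5"]], a[["1"]] - 0.05)
    expect_gte(a[["30"]], a[["5"]] - 0.1)      # plateau, no collapse
    expect_error(topkAccuracyCurve(rk, train, val, ks = 31), "between")

    # k = J uses every gene, so the ranking order cannot matter
    shuffled <- GeneRanking(setNames(rev(seq_len(30)) * 1.0, geneIds(d)))
    expect_equal(topkAccuracyCurve(rk, train, val, ks = 30, seed = 1),
                 topkAccuracyCurve(shuffled, train, val, ks = 30, seed = 1))
})

test_that("LOOCV runs N fits and matches an exhaustive manual loop", {
    m <- matrix(c(1, 5,
                  2, 6,
                  9, 1,
                  10, 2), 4, 2, byrow = TRUE,
                dimnames = list(paste0("s", 1:4), c("g1", "g2")))
    d <- DIDataSet(m, c("lo", "lo", "hi", "hi"))
    res <- loocvAccuracy(d, classifier = "softmax", seed = 4)
    expect_identical(res$nFits, 4L)
    # hand-enumerated folds with the same classifier and seed
    manual <- vapply(1:4, function(i) {
        fit <- fitSoftmax(d[, -i], trainControl(), seed = 4)
        p <- predictProba(fit, exprValues(d)[i, ])
        names(which.max(p)) == as.character(classLabels(d))[i]
    }, logical(1))
    expect_equal(res$accuracy, mean(manual))
    expect_true(res$accuracy * 4 == round(res$accuracy * 4))  # multiples of 1/N
})

test_that("LOOCV is perfect on a cleanly separable cohort", {
    d <- separableDataset(nPerClass = 10, j = 2, seed = 23)
    res <- loocvAccuracy(d, classifier = "xgboost", seed = 1, nrounds = 20)
    expect_equal(res$accuracy, 1.0)
    expect_identical(res$nFits, 20L)
})

test_that("LOOCV refuses singleton classes", {
    m <- toyMatrix(n = 5, j = 3)
    d <- DIDataSet(m, c("a", "a", "a", "a", "b"))
    expect_error(loocvAccuracy(d), "at least 2 samples")
})

test_that("ranking overlap reproduces printed percentages", {
    # 45 of the top 500 shared -> 9.0%; 379 of the top 2000 -> 19.0%
    a500 <- paste0("a", 1:500)
    b500 <- c(paste0("a", 1:45), paste0("b", 1:455))
    expect_equal(rankingOverlap(a500, b500, 500)$overlap, 9.0)
    a2k <- paste0("a", 1:2000)
    b2k <- c(paste0("a", 1:379), paste0("b", 1:1621))
    expect_equal(rankingOverlap(a2k, b2k, 2000)$overlap, 19.0)
})

test_that("overlap is symmetric, bounded and exact on identical lists", {
    set.seed(40)
    a <- sample(paste0("g", 1:300))
    b <- sample(paste0("g", 1:300))
    depths <- c(1, 10, 50, 300)
    oab <- rankingOverlap(a, b, depths)
    oba <- rankingOverlap(b, a, depths)
    expect_equal(oab, oba)
    expect_true(all(oab$overlap >= 0 & oab$overlap <= 100))
    expect_equal(rankingOverlap(a, a, depths)$overlap, rep(100, 4))
    expect_error(rankingOverlap(a, b, 0), "positive")
    expect_error(rankingOverlap(a, b, 301), "exceeds")
})

test_that("the AUC helper scores a clean separation as 1", {
    lab <- factor(rep(c("n", "t"), each = 10))
    expect_equal(aucScore(c(rnorm(10, 0), rnorm(10, 10)), lab), 1)
})

test_that("pan-cancer cohort bookkeeping table loads", {
    cc <- pancancerCohorts()
    expect_identical(nrow(cc), 12L)
    expect_identical(cc$total, cc$cancer + cc$normal)
})
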