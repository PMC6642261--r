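test_that("class means are plain arithmetic means", {
    m <- matrix(c(0, 2,
                  4, 6,
                  1, 1), 3, 2, byrow = TRUE,
                dimnames = list(paste0("s", 1:3), c("g1", "g2")))
    d <- DIDataSet(m, c("a", "a", "b"))
    cm <- classMeans(d)
    expect_equal(unname(cm["a", ]), c(2, 4))     # mean of (0,4) and (2,6)
    expect_equal(unname(cm["b", ]), c(1, 1))     # single sample = itself
})

test_that("class means are invariant to sample order", {
    d <- separableDataset(nPerClass = 6, j = 4, seed = 3)
    perm <- sample(ncol(d))
    expect_equal(classMeans(d), classMeans(d[, perm]))
})

test_that("weight-times-mean products are elementwise, excluding bias", {
    W <- matrix(c(2, -1,
                  0, 3), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("g1", "g2")))
    means <- matrix(c(3, 4,
                      1, 2), 2, 2, byrow = TRUE, dimnames = dimnames(W))
    wx <- wxVectors(W, means)
    expect_equal(unname(wx["a", ]), c(6, -4))
    expect_equal(wxVectors(W * 0, means), means * 0)
    expect_equal(wxVectors(W * 3, means), wx * 3)       # linear in weights
    expect_error(wxVectors(W, means[, 1, drop = FALSE]), "shape mismatch")
})

test_that("DI sums |differences| over all unordered class pairs", {
    wx <- randomWX(4, 6, seed = 10)
    di <- discriminativeIndex(wx)
    expect_identical(nPairs(di), 6L)             # 4 * 3 / 2 pairs
    expect_equal(diScores(di), bruteForceDI(wx), tolerance = 1e-12)
    expect_true(all(diScores(di) >= 0))

    wx3 <- randomWX(3, 5, seed = 11)
    expect_identical(nPairs(discriminativeIndex(wx3)), 3L)

    same <- matrix(7, 3, 4, dimnames = list(NULL, paste0("g", 1:4)))
    expect_equal(unname(diScores(discriminativeIndex(same))), rep(0, 4))
    expect_error(discriminativeIndex(wx[1, , drop = FALSE]), "2 classes")
})

test_that("DI ties break by ascending gene id", {
    wx <- matrix(c(0, 0, 0,
                   1, 1, 2), 2, 3, byrow = TRUE,
                 dimnames = list(NULL, c("zeta", "alpha", "mid")))
    di <- discriminativeIndex(wx)
    expect_identical(sortedGenes(di), c("mid", "alpha", "zeta"))
})

test_that("one ranking pass is deterministic and permutation-equivariant", {
    d <- separableDataset(nPerClass = 8, j = 6, seed = 12)
    di1 <- runDIOnce(d, seed = 5)
    di2 <- runDIOnce(d, seed = 5)
    expect_identical(diScores(di1), diScores(di2))

    # shuffling gene columns permutes DI identically
    perm <- c(4, 1, 6, 2, 5, 3)
    dPerm <- d[perm, ]
    diP <- runDIOnce(dPerm, seed = 5)
    expect_equal(diScores(diP), diScores(di1)[perm], tolerance = 1e-12)

    # shuffling samples leaves DI untouched (full-batch training)
    set.seed(1); sPerm <- sample(ncol(d))
    expect_equal(diScores(runDIOnce(d[, sPerm], seed = 5)), diScores(di1),
                 tolerance = 1e-12)
})

test_that("DI is linear in the weights at fixed class means", {
    d <- separableDataset(nPerClass = 6, j = 5, seed = 13)
    fit <- fitSoftmax(d, seed = 2)
    means <- classMeans(d)
    di1 <- diScores(discriminativeIndex(wxVectors(fit@weights, means)))
    di3 <- diScores(discriminativeIndex(wxVectors(fit@weights * 3, means)))
    expect_equal(di3, di1 * 3, tolerance = 1e-12)
})

test_that("averaged ranking matches its single runs", {
    d <- separableDataset(nPerClass = 6, j = 8, seed = 14)
    # nIter = 1 equals the single pass at the derived seed (base + 1)
    rk1 <- rankGenes(d, nIter = 1, seed = 20)
    one <- diScores(runDIOnce(d, seed = 21))
    expect_equal(rankingTable(rk1)$mean_di,
                 sort(unname(one), decreasing = TRUE), tolerance = 1e-12)

    # nIter = 2 is the elementwise average of the two runs
    rk2 <- rankGenes(d, nIter = 2, seed = 20)
    avg <- (diScores(runDIOnce(d, seed = 21)) +
            diScores(runDIOnce(d, seed = 22))) / 2
    tab <- rankingTable(rk2)
    expect_equal(tab$mean_di, unname(avg[tab$gene_id]), tolerance = 1e-12)
    expect_false(is.unsorted(rev(tab$mean_di)))
})

test_that("the reference iteration count is 10,000", {
    expect_identical(formals(getMethod("rankGenes", "DIDataSet"))$nIter,
                     10000L)
})

test_that("top-c selection slices the ranking in order", {
    scores <- setNames(seq(20, 1), paste0("g", sprintf("%02d", 1:20)))
    rk <- GeneRanking(scores)
    expect_identical(topGenes(rk, 14), paste0("g", sprintf("%02d", 1:14)))
    expect_identical(topGenes(rk, 20), rankingTable(rk)$gene_id)
    expect_identical(topGenes(rk, 1), "g01")
    expect_error(topGenes(rk, 0), "between 1 and 20")
    expect_error(topGenes(rk, 21), "between 1 and 20")
})

test_that("resplit-per-iteration mode still ranks the planted signal first", {
    sim <- simulateExpression(nPerClass = c(cancer = 30, normal = 30),
                              nGenes = 50, plantedGenes = 1, seed = 31)
    rk <- rankGenes(sim$dataset, nIter = 5, seed = 3,
                    resplitFraction = 0.5)
    expect_identical(topGenes(rk, 1), plantedIds(sim$truth))
})
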