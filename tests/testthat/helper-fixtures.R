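# fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir()

# tiny deterministic matrix with named dims
toyMatrix <- function(n = 4, j = 3, seed = 1) {
    set.seed(seed)
    matrix(round(abs(rnorm(n * j, 10, 3)), 3), n, j,
           dimnames = list(paste0("s", seq_len(n)),
                           paste0("g", seq_len(j))))
}

# two classes cleanly separated on gene g1 (class A ~ 0, class B ~ 10),
# remaining genes pure noise
separableDataset <- function(nPerClass = 10, j = 2, seed = 1) {
    set.seed(seed)
    n <- 2 * nPerClass
    m <- matrix(abs(rnorm(n * j, 5, 1)), n, j,
                dimnames = list(paste0("s", seq_len(n)),
                                paste0("g", seq_len(j))))
    m[, 1] <- c(abs(rnorm(nPerClass, 0, 0.05)),
                rnorm(nPerClass, 10, 0.05))
    DIDataSet(m, rep(c("A", "B"), each = nPerClass))
}

# random weight / class-mean pair for DI oracle checks
randomWX <- function(K, J, seed) {
    set.seed(seed)
    matrix(rnorm(K * J, 0, 5), K, J,
           dimnames = list(paste0("class", seq_len(K)),
                           paste0("g", seq_len(J))))
}

# independent brute-force DI: explicit double loop over unordered pairs
bruteForceDI <- function(wx) {
    K <- nrow(wx)
    di <- numeric(ncol(wx))
    for (j in seq_len(ncol(wx))) {
        total <- 0
        for (k1 in seq_len(K - 1))
            for (k2 in (k1 + 1):K)
                total <- total + abs(wx[k1, j] - wx[k2, j])
        di[j] <- total
    }
    names(di) <- colnames(wx)
    di
}

cliScript <- function() {
    system.file("cli", "diselect.R", package = "DIselect", mustWork = TRUE)
}

runCli <- function(...) {
    out <- suppressWarnings(
        system2("Rscript", c(cliScript(), ...), stdout = TRUE,
                stderr = TRUE))
    status <- attr(out, "status")
    list(status = if (is.null(status)) 0L else status, output = out)
}
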