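# Shared fixtures built in code.

# tiny deterministic spectra matrix
tinySpectra <- function(n = 3, p = 5, seed = 7, wn = NULL) {
    set.seed(seed)
    if (is.null(wn)) wn <- seq(4000, by = 8, length.out = p)
    SpectraMatrix(matrix(rnorm(n * p), n, p), wn, paste0("S", seq_len(n)))
}

# small simulated dataset (cheap default for unit tests)
smallSim <- function(seed = 1, n = c(10, 8, 8), ...) {
    simulateDataset(SyntheticConfig(nPerRegion = n, seed = seed, ...))
}

# a low-resolution axis config so heavier simulations stay fast
coarseConfig <- function(seed = 1, ...) {
    SyntheticConfig(axis = seq(4000, 12000, by = 40), seed = seed, ...)
}

tablePath <- function(name) system.file("extdata", name, package = "poriaNIR")

# Exhaustive max-min reference implementation of Kennard-Stone selection.
ksOracle <- function(X, k) {
    D <- as.matrix(dist(X))
    n <- nrow(X)
    best <- c(1L, 2L); bd <- -Inf
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
        if (D[i, j] > bd) { bd <- D[i, j]; best <- c(i, j) }
    sel <- best
    while (length(sel) < k) {
        cand <- setdiff(seq_len(n), sel)
        mind <- vapply(cand, function(i) min(D[i, sel]), numeric(1))
        sel <- c(sel, cand[which.max(mind)])
    }
    sel
}
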