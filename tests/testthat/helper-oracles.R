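# Independent oracles used across test files. These deliberately avoid the
# code paths they check.

# One-sided enrichment p for a 2x2 table by explicit combinatorial
# enumeration: sum hypergeometric masses over all tables at least as
# enriched (x >= k), computed from binomial coefficients.
fisherEnumOracle <- function(k, K, n, N) {
    xs <- max(0, k):min(K, n)
    sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Unsigned TOM by direct triple loop over shared neighbours.
tomOracle <- function(a) {
    p <- nrow(a)
    k <- rowSums(a) - 1
    tom <- diag(p)
    for (i in seq_len(p)) for (j in seq_len(p)) {
        if (i == j) next
        l <- 0
        for (u in seq_len(p)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
        tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
    dimnames(tom) <- dimnames(a)
    tom
}

# Planted two-module developmental fixture shared by several files.
makePlantedDevelopment <- function(seed = 11L, nGenes = 99L, m1 = 47L,
                                   m2 = 22L, ...) {
    simulateDevelopmentMatrix(nGenes = nGenes, module1Size = m1,
                              module2Size = m2, seed = seed, ...)
}

truthLabelsOf <- function(truth) {
    lab <- rep(c(1L, 2L, 0L), c(length(truth$module1), length(truth$module2),
                                length(truth$background)))
    names(lab) <- c(truth$module1, truth$module2, truth$background)
    lab
}
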