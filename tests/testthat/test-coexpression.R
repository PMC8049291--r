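test_that("fold-change normalization is per-gene and scale invariant", {
    m <- rbind(g1 = c(4, 4, 0), g2 = c(2, 2, 2), g3 = c(0, 0, 0))
    expect_warning(norm <- normalizeFoldChange(m), "zero mean")
    expect_false("g3" %in% rownames(norm))
    # limit behaviour: value 4 against gene mean 2 gives ~1 (eps = 1e-3)
    norm0 <- normalizeFoldChange(rbind(g = c(4, 2, 1, 1)), eps = 1e-9)
    expect_equal(unname(norm0["g", 1]), 1, tolerance = 1e-6)
    # a constant gene normalizes to all zeros
    expect_true(all(abs(norm["g2", ]) < 1e-9))
    # doubling every raw value leaves the profile unchanged
    a <- normalizeFoldChange(rbind(g = c(1, 2, 8, 16)), eps = 1e-9)
    b <- normalizeFoldChange(rbind(g = 2 * c(1, 2, 8, 16)), eps = 1e-9)
    expect_equal(a, b, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("TOM equals the brute-force triple-loop oracle", {
    withr::local_seed(8)
    for (i in 1:10) {
        p <- sample(4:12, 1)
        X <- matrix(rnorm(p * 20), p,
                    dimnames = list(paste0("g", 1:p), NULL))
        net <- buildNetwork(X, power = 7)
        expect_equal(net$tom, tomOracle(net$adjacency), tolerance = 1e-12)
        # symmetry, range and unit diagonal of both matrices
        for (M in list(net$adjacency, net$tom)) {
            expect_true(isSymmetric(unname(M)))
            expect_true(all(M >= -1e-12 & M <= 1 + 1e-12))
            expect_equal(unname(diag(M)), rep(1, p))
        }
    }
})

test_that("TOM has the expected closed forms in degenerate networks", {
    # three genes with all pairwise |cor| = 1: fully connected network
    X <- rbind(g1 = c(1, 2, 3, 4, 5), g2 = 2 * c(1, 2, 3, 4, 5),
               g3 = -c(1, 2, 3, 4, 5))
    net <- buildNetwork(X, power = 7)
    expect_equal(unname(net$adjacency), matrix(1, 3, 3))
    expect_equal(unname(net$tom), matrix(1, 3, 3))
    # orthogonal third gene: TOM_12 collapses to a_12 (the 2-gene closed form)
    v1 <- c(1, 1, -1, -1); v2 <- c(1, -1, 1, -1); v3 <- c(1, -1, -1, 1)
    X <- rbind(g1 = v1, g2 = 3 * v1 + 4 * v2, g3 = v3)  # cor(g1,g2) = 0.6
    net <- buildNetwork(X, power = 7)
    expect_equal(net$adjacency["g1", "g2"], 0.6^7, tolerance = 1e-12)
    expect_equal(net$tom["g1", "g2"], 0.6^7, tolerance = 1e-12)
})

test_that("zero-variance genes are dropped before correlation", {
    X <- rbind(g1 = rnorm(10), g2 = rnorm(10), g3 = rnorm(10),
               flat = rep(1, 10))
    expect_warning(net <- buildNetwork(X), "zero-variance")
    expect_identical(rownames(net$adjacency), c("g1", "g2", "g3"))
})

test_that("module detection recovers planted structure exactly when perfect", {
    # perfect two-block TOM
    tom <- matrix(0, 25, 25, dimnames = list(paste0("g", 1:25),
                                             paste0("g", 1:25)))
    tom[1:15, 1:15] <- 1
    tom[16:25, 16:25] <- 1
    asg <- detectModules(tom, minModuleSize = 5)
    expect_identical(unname(moduleSizes(asg)), c(15L, 10L))
    expect_identical(unname(moduleLabels(asg)), rep(c(1L, 2L), c(15, 10)))
    # all-identical genes: one module containing everything
    asg <- detectModules(matrix(1, 12, 12), minModuleSize = 5)
    expect_identical(unname(moduleSizes(asg)), 12L)
    # nothing below the cut: zero modules is a valid outcome
    asg <- detectModules(diag(12), minModuleSize = 5, cutHeight = 0.85)
    expect_length(moduleSizes(asg), 0L)
    expect_true(all(moduleLabels(asg) == 0L))
})

test_that("planted 47/22 modules are recovered with correct temporal classes", {
    dv <- makePlantedDevelopment(seed = 11)
    norm <- normalizeFoldChange(dv$experiment)
    net <- buildNetwork(norm, power = 7)
    asg <- detectModules(net)
    expect_length(moduleSizes(asg), 2L)
    truth <- truthLabelsOf(dv$truth)
    ari <- mclust::adjustedRandIndex(moduleLabels(asg)[names(truth)], truth)
    expect_gte(ari, 0.9)
    asg <- summarizeModules(asg, norm, dv$experiment)
    expect_identical(temporalClass(asg), c("postnatal_high", "prenatal_high"))
    # noise genes end up unassigned
    expect_gte(sum(moduleLabels(asg)[dv$truth$background] == 0L), 25)
})

test_that("module labels are invariant under gene permutation", {
    dv <- makePlantedDevelopment(seed = 12, nGenes = 40, m1 = 15, m2 = 10)
    norm <- normalizeFoldChange(dv$experiment)
    asg1 <- detectModules(buildNetwork(norm))
    withr::local_seed(1)
    perm <- sample(nrow(norm))
    asg2 <- detectModules(buildNetwork(norm[perm, ]))
    l1 <- moduleLabels(asg1)
    l2 <- moduleLabels(asg2)[names(l1)]
    expect_identical(l1, l2)   # relabeling by size is permutation-stable here
})

test_that("eigengenes are unit norm, sign-aligned and first-PC optimal", {
    dv <- makePlantedDevelopment(seed = 13, nGenes = 40, m1 = 15, m2 = 10)
    norm <- normalizeFoldChange(dv$experiment)
    asg <- summarizeModules(detectModules(buildNetwork(norm)), norm,
                            dv$experiment)
    eg <- eigengenes(asg)
    withr::local_seed(2)
    for (m in seq_len(ncol(eg))) {
        e <- eg[, m]
        expect_equal(sum(e^2), 1, tolerance = 1e-8)
        members <- names(moduleLabels(asg))[moduleLabels(asg) == m]
        M <- norm[members, , drop = FALSE]
        Z <- t(scale(t(M))); Z[!is.finite(Z)] <- 0
        expect_gt(cor(e, colMeans(M)), 0)           # sign alignment
        vE <- sum((Z %*% e)^2)
        for (i in 1:20) {                            # PC1 beats random dirs
            r <- rnorm(length(e)); r <- r / sqrt(sum(r^2))
            expect_gte(vE, sum((Z %*% r)^2) - 1e-8)
        }
    }
})

test_that("a flat module is temporally indeterminate", {
    dv <- simulateDevelopmentMatrix(nGenes = 12, module1Size = 0,
                                    module2Size = 0, amplitude = 0,
                                    missingFraction = 0, seed = 5)
    norm <- normalizeFoldChange(dv$experiment)
    # force all genes into one module to probe the classifier
    asg <- detectModules(matrix(1, 12, 12,
                                dimnames = list(rownames(norm),
                                                rownames(norm))),
                         minModuleSize = 5)
    asg <- summarizeModules(asg, norm, dv$experiment)
    expect_identical(temporalClass(asg), "indeterminate")
    expect_identical(dim(asg@temporalProfiles), c(1L, 12L))
    expect_identical(dim(asg@spatialProfiles), c(1L, 16L))
})

test_that("no modules arise from pure noise", {
    hits <- 0L
    for (s in 1:10) {
        dv <- simulateDevelopmentMatrix(nGenes = 60, module1Size = 0,
                                        module2Size = 0, seed = 100 + s)
        asg <- detectModules(buildNetwork(normalizeFoldChange(dv$experiment)))
        hits <- hits + (length(moduleSizes(asg)) > 0L)
    }
    expect_lte(hits, 1L)
})
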