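test_that("log2 display normalization follows the conversion formula", {
    expect_identical(normalizeLog2(7), 3)
    expect_identical(normalizeLog2(0), 0)
    expect_identical(normalizeLog2(15), 4)
    expect_error(normalizeLog2(-1), ">= 0")
})

test_that("exact rank-sum enumeration reproduces hand-computable cases", {
    ts <- rankSumTest(1:3, 4:6)
    expect_identical(ts$method, "exact")
    expect_identical(ts$statistic, 0)
    expect_equal(ts$p.value, 0.1)           # 2 of the C(6,3)=20 labelings
    # one-sided versions
    expect_equal(rankSumTest(1:3, 4:6, "less")$p.value, 0.05)
    expect_equal(rankSumTest(4:6, 1:3, "greater")$p.value, 0.05)
    # identical multisets are maximally non-significant
    expect_equal(rankSumTest(c(1, 2, 3), c(3, 1, 2))$p.value, 1)
    # fully degenerate input
    d <- rankSumTest(rep(2, 5), rep(2, 7))
    expect_equal(d$p.value, 1)
    expect_equal(d$statistic, 5 * 7 / 2)
})

test_that("rank-sum statistic and labels obey the symmetry properties", {
    withr::local_seed(5)
    for (i in 1:20) {
        x <- rnorm(sample(3:30, 1))
        y <- rnorm(sample(3:30, 1))
        ux <- rankSumTest(x, y)$statistic
        uy <- rankSumTest(y, x)$statistic
        expect_equal(ux + uy, length(x) * length(y))      # U_x + U_y = n1 n2
        expect_equal(rankSumTest(x, y)$p.value, rankSumTest(y, x)$p.value)
        # invariance under strictly monotone transforms of the pooled values
        expect_equal(rankSumTest(exp(x), exp(y))$p.value,
                     rankSumTest(x, y)$p.value)
    }
})

test_that("exact and approximate branches agree on tie-free (5,5) samples", {
    # the worst-case gap of the corrected normal approximation at (5,5) is
    # 0.0086 one-sided and exactly twice that two-sided (both tails double)
    withr::local_seed(6)
    for (i in 1:40) {
        x <- rnorm(5); y <- rnorm(5)
        for (alt in c("greater", "less")) {
            pe <- rankSumTest(x, y, alt, exact = TRUE)$p.value
            pa <- rankSumTest(x, y, alt, exact = FALSE)$p.value
            expect_lt(abs(pe - pa), 0.01)
        }
        pe <- rankSumTest(x, y, exact = TRUE)$p.value
        pa <- rankSumTest(x, y, exact = FALSE)$p.value
        expect_lt(abs(pe - pa), 0.02)
    }
    expect_error(rankSumTest(c(1, 1, 2), c(2, 3, 4), exact = TRUE), "tie")
})

test_that("approximation matches wilcox.test's corrected normal p", {
    withr::local_seed(7)
    for (i in 1:15) {
        x <- round(rnorm(45, sd = 2), 1)   # rounding induces ties
        y <- round(rnorm(24, sd = 2), 1)
        ours <- rankSumTest(x, y)
        ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                   correct = TRUE))
        expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
        expect_equal(ours$statistic, unname(ref$statistic))
    }
})

test_that("planted class shifts are classified in the planted direction", {
    ns <- simulateNeuronMatrix(nGenes = 60, nExcShifted = 10, nInhShifted = 8,
                               shiftEffect = 16, noiseSd = 0.3, seed = 21)
    prof <- profileNeuronTypes(ns$experiment, rownames(ns$experiment))
    dir <- setNames(prof$direction, prof$gene)
    expect_true(all(dir[ns$truth$excShifted] == "excitatory_higher"))
    expect_true(all(dir[ns$truth$inhShifted] == "inhibitory_higher"))
    expect_true(all(prof$U >= 0 & prof$U <= prof$n_inh * prof$n_exc))
    # direction labels flip when the class tags are swapped
    swapped <- ns$experiment
    cd <- SummarizedExperiment::colData(swapped)
    cd$neuron_class <- c(inhibitory = "excitatory",
                         excitatory = "inhibitory",
                         non_neuronal = "non_neuronal")[cd$neuron_class]
    SummarizedExperiment::colData(swapped) <- cd
    prof2 <- profileNeuronTypes(swapped, rownames(swapped))
    dir2 <- setNames(prof2$direction, prof2$gene)
    expect_true(all(dir2[ns$truth$excShifted] == "inhibitory_higher"))
})

test_that("genes absent from the matrix are skipped, not fatal", {
    ns <- simulateNeuronMatrix(nGenes = 10, nExcShifted = 2, nInhShifted = 2,
                               seed = 2)
    expect_warning(prof <- profileNeuronTypes(
        ns$experiment, c(rownames(ns$experiment), "MISSING1")), "skipped")
    expect_identical(nrow(prof), 10L)
    expect_identical(S4Vectors::metadata(prof)$skipped, "MISSING1")
})

test_that("summary percentages are formatted to two decimals", {
    fake <- S4Vectors::DataFrame(
        gene = paste0("g", 1:107),
        direction = rep(c("excitatory_higher", "inhibitory_higher",
                          "no_difference"), c(34, 23, 50)))
    s <- neuronSummary(fake)
    expect_identical(s$n_diff, 57L)
    expect_identical(s$pct_exc_higher, "59.65%")
    expect_identical(s$pct_inh_higher, "40.35%")
    expect_identical(s$n_exc_higher + s$n_inh_higher, s$n_diff)
})
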