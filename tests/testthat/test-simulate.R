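test_that("all four generators are deterministic under a fixed seed", {
    a <- simulateTissueMatrix(nGenes = 30, nSignalGenes = 5, seed = 7)
    b <- simulateTissueMatrix(nGenes = 30, nSignalGenes = 5, seed = 7)
    expect_identical(SummarizedExperiment::assay(a$experiment),
                     SummarizedExperiment::assay(b$experiment))
    expect_identical(a$truth, b$truth)

    a <- simulateNeuronMatrix(20, 3, 2, seed = 7)
    b <- simulateNeuronMatrix(20, 3, 2, seed = 7)
    expect_identical(SummarizedExperiment::assay(a$experiment),
                     SummarizedExperiment::assay(b$experiment))

    a <- simulateDevelopmentMatrix(20, 5, 5, seed = 7)
    b <- simulateDevelopmentMatrix(20, 5, 5, seed = 7)
    expect_identical(SummarizedExperiment::assay(a$experiment),
                     SummarizedExperiment::assay(b$experiment))

    tr <- a$truth
    expect_identical(simulateAAO(tr, seed = 7), simulateAAO(tr, seed = 7))
    # a different seed changes the draw
    expect_false(identical(simulateAAO(tr, seed = 7),
                           simulateAAO(tr, seed = 8)))
})

test_that("generator truth labels are consistent and disjoint", {
    ts <- simulateTissueMatrix(nGenes = 50, nSignalGenes = 10, seed = 3)
    expect_true(all(ts$truth$signalGenes %in% rownames(ts$experiment)))
    expect_true(all(ts$truth$brainTissues %in% colnames(ts$experiment)))
    expect_length(ts$truth$brainTissues, 13L)

    ns <- simulateNeuronMatrix(40, 6, 4, seed = 3)
    tr <- ns$truth
    expect_length(intersect(tr$excShifted, tr$inhShifted), 0L)
    expect_setequal(c(tr$excShifted, tr$inhShifted, tr$background),
                    rownames(ns$experiment))

    dv <- simulateDevelopmentMatrix(30, 10, 5, seed = 3)
    tr <- dv$truth
    expect_setequal(c(tr$module1, tr$module2, tr$background),
                    rownames(dv$experiment))
    expect_length(intersect(tr$module1, tr$module2), 0L)
})

test_that("neuron annotation carries the 45+24+6 class structure", {
    ns <- simulateNeuronMatrix(10, 1, 1, seed = 1)
    cd <- SummarizedExperiment::colData(ns$experiment)
    expect_identical(ncol(ns$experiment), 75L)
    expect_identical(as.vector(table(cd$neuron_class)[c("inhibitory",
        "excitatory", "non_neuronal")]), c(45L, 24L, 6L))
    expect_false(anyDuplicated(cd$neuron_type) > 0)
})

test_that("development samples map to the region x stage grid with gaps", {
    dv <- simulateDevelopmentMatrix(10, 3, 3, missingFraction = 0.2, seed = 2)
    cd <- SummarizedExperiment::colData(dv$experiment)
    expect_identical(ncol(dv$experiment), as.integer(round(0.8 * 16 * 12)))
    expect_true(all(cd$stage_index %in% 1:12))
    expect_identical(as.integer(cd$prenatal), as.integer(cd$stage_index <= 6))
    expect_length(unique(cd$region), 16L)
})

test_that("invalid generator configs are rejected", {
    expect_error(simulateTissueMatrix(10, 20, seed = 1), "nSignalGenes")
    expect_error(simulateTissueMatrix(10, 2, brainEffect = 0.5, seed = 1),
                 "brainEffect")
    expect_error(simulateTissueMatrix(10, 2, brainTissueCount = 60,
                                      nTissues = 53, seed = 1),
                 "brainTissueCount")
    expect_error(simulateNeuronMatrix(10, 6, 6, seed = 1), "<=")
    expect_error(simulateDevelopmentMatrix(10, 4, 4, nTimepoints = 11,
                                           seed = 1), "even")
    expect_error(simulateDevelopmentMatrix(10, 8, 8, seed = 1), "<=")
    expect_error(simulateAAO(list(module1 = "A", module2 = "B",
                                  background = character(0)),
                             m1Median = -4, seed = 1), "positive")
})

test_that("simulated AAO records are positive and follow module centers", {
    truth <- list(module1 = paste0("A", 1:8), module2 = paste0("B", 1:8),
                  background = paste0("C", 1:4))
    aao <- simulateAAO(truth, perGeneN = 30, m1Median = 35, m2Median = 55,
                       spreadSd = 5, seed = 9)
    expect_true(all(aao$aao_years > 0))
    expect_identical(nrow(aao), 20L * 30L)
    m1med <- median(aao$aao_years[aao$gene %in% truth$module1])
    m2med <- median(aao$aao_years[aao$gene %in% truth$module2])
    expect_lt(m1med, m2med)
    expect_lt(abs(m1med - 35), 3)
    expect_lt(abs(m2med - 55), 3)
})

test_that("null effects make planted and background genes exchangeable", {
    # brainEffect = 1: signal genes show no preferential-tissue excess
    ts <- simulateTissueMatrix(nGenes = 400, nSignalGenes = 50,
                               brainEffect = 1, seed = 13)
    enr <- enrichTissues(ts$experiment, ts$truth$signalGenes)
    expect_lte(sum(enr$significant), 3)  # ~0.53 expected at alpha = 0.01
})
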