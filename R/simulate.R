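#' Simulate a per-tissue mean expression table with a brain-elevated subset
#'
#' Emulates a consortium-style tissue expression resource summarized to one
#' mean expression profile per tissue: each cell is drawn log-normally
#' (normal on the log2 scale, then exponentiated, giving the heavy right
#' tail typical of RPKM-like data) and a planted subset of "signal" genes
#' has its expression multiplied by \code{brainEffect} in the brain tissues.
#' With \code{brainEffect = 1} signal and background genes are exchangeable
#' (the null case for enrichment calibration).
#'
#' @param nGenes number of genes.
#' @param nSignalGenes number of brain-elevated genes (randomly placed).
#' @param nTissues number of tissues (default 53, the tissue-ranking
#'   universe used throughout).
#' @param brainTissueCount number of brain tissues (default 13).
#' @param brainEffect fold multiplier (>= 1) applied to signal genes in
#'   brain tissues.
#' @param baseLogMean,baseLogSd mean and sd of baseline expression on the
#'   log2 scale.
#' @param seed integer RNG seed; identical seed implies identical output.
#' @return list with \code{experiment} (a \linkS4class{PagExperiment}, role
#'   "tissue") and \code{truth} (list: \code{signalGenes},
#'   \code{brainTissues}).
#' @examples
#' sim <- simulateTissueMatrix(nGenes = 50, nSignalGenes = 5, seed = 1)
#' sim$experiment
#' @export
simulateTissueMatrix <- function(nGenes, nSignalGenes, nTissues = 53L,
                                 brainTissueCount = 13L, brainEffect = 8,
                                 baseLogMean = 3, baseLogSd = 2, seed = 1L) {
    nGenes <- .checkCount(nGenes, "nGenes", 1L)
    nSignalGenes <- .checkCount(nSignalGenes, "nSignalGenes")
    nTissues <- .checkCount(nTissues, "nTissues", 2L)
    brainTissueCount <- .checkCount(brainTissueCount, "brainTissueCount", 1L)
    if (brainTissueCount > nTissues)
        stop("'brainTissueCount' must be <= 'nTissues'")
    if (nSignalGenes > nGenes)
        stop("'nSignalGenes' must be <= 'nGenes'")
    if (!is.finite(brainEffect) || brainEffect < 1)
        stop("'brainEffect' must be >= 1")
    if (baseLogSd <= 0) stop("'baseLogSd' must be positive")

    genes <- paste0("GENE", zeroPad(seq_len(nGenes), nGenes))
    tissues <- c(paste0("brain_", zeroPad(seq_len(brainTissueCount),
                                          brainTissueCount)),
                 if (nTissues > brainTissueCount)
                     paste0("tissue_", zeroPad(seq_len(nTissues - brainTissueCount),
                                               nTissues)))
    out <- withSeed(seed, {
        expr <- matrix(2^stats::rnorm(nGenes * nTissues, baseLogMean,
                                      baseLogSd),
                       nrow = nGenes, dimnames = list(genes, tissues))
        signal <- sort(sample(genes, nSignalGenes))
        expr[signal, seq_len(brainTissueCount)] <-
            expr[signal, seq_len(brainTissueCount)] * brainEffect
        list(expr = expr, signal = signal)
    })
    exp <- PagExperiment(out$expr,
                         data.frame(tissue = tissues, row.names = tissues),
                         role = "tissue", metadata = list(seed = seed))
    list(experiment = exp,
         truth = list(signalGenes = out$signal,
                      brainTissues = tissues[seq_len(brainTissueCount)]))
}

#' Simulate per-neuron-type mean expression with class-shifted genes
#'
#' One column per transcriptomic neuron type (default 45 inhibitory, 24
#' excitatory, 6 non-neuronal, mirroring a cortical single-nucleus
#' taxonomy). Planted genes have their means multiplied by
#' \code{shiftEffect} in all excitatory (or all inhibitory) columns; the
#' remaining genes are exchangeable across types, so with
#' \code{shiftEffect = 1} the rank-sum test is exactly calibrated.
#'
#' @param nGenes number of genes.
#' @param nExcShifted,nInhShifted numbers of genes shifted toward the
#'   excitatory / inhibitory class.
#' @param nInhibitory,nExcitatory,nNonNeuronal numbers of neuron types per
#'   class.
#' @param shiftEffect fold multiplier (>= 1) for shifted genes.
#' @param noiseSd per-type log2-scale noise sd.
#' @param baseLogMean,baseLogSd gene-baseline distribution on log2 scale.
#' @param seed integer RNG seed.
#' @return list with \code{experiment} (role "neuron") and \code{truth}
#'   (list: \code{excShifted}, \code{inhShifted}, \code{background}).
#' @export
simulateNeuronMatrix <- function(nGenes, nExcShifted, nInhShifted,
                                 nInhibitory = 45L, nExcitatory = 24L,
                                 nNonNeuronal = 6L, shiftEffect = 8,
                                 noiseSd = 1, baseLogMean = 3,
                                 baseLogSd = 2, seed = 1L) {
    nGenes <- .checkCount(nGenes, "nGenes", 1L)
    nExcShifted <- .checkCount(nExcShifted, "nExcShifted")
    nInhShifted <- .checkCount(nInhShifted, "nInhShifted")
    nInhibitory <- .checkCount(nInhibitory, "nInhibitory", 1L)
    nExcitatory <- .checkCount(nExcitatory, "nExcitatory", 1L)
    nNonNeuronal <- .checkCount(nNonNeuronal, "nNonNeuronal")
    if (nExcShifted + nInhShifted > nGenes)
        stop("'nExcShifted' + 'nInhShifted' must be <= 'nGenes'")
    if (!is.finite(shiftEffect) || shiftEffect < 1)
        stop("'shiftEffect' must be >= 1")
    if (noiseSd <= 0) stop("'noiseSd' must be positive")

    genes <- paste0("GENE", zeroPad(seq_len(nGenes), nGenes))
    types <- c(paste0("Inh_", zeroPad(seq_len(nInhibitory), nInhibitory)),
               paste0("Exc_", zeroPad(seq_len(nExcitatory), nExcitatory)),
               if (nNonNeuronal > 0)
                   paste0("NonNeu_", zeroPad(seq_len(nNonNeuronal),
                                             nNonNeuronal)))
    classes <- rep(c("inhibitory", "excitatory", "non_neuronal"),
                   c(nInhibitory, nExcitatory, nNonNeuronal))
    nTypes <- length(types)
    out <- withSeed(seed, {
        base <- stats::rnorm(nGenes, baseLogMean, baseLogSd)
        expr <- 2^(base + matrix(stats::rnorm(nGenes * nTypes, 0, noiseSd),
                                 nrow = nGenes))
        dimnames(expr) <- list(genes, types)
        shifted <- sample(genes, nExcShifted + nInhShifted)
        excShifted <- sort(utils::head(shifted, nExcShifted))
        inhShifted <- sort(utils::tail(shifted, nInhShifted))
        expr[excShifted, classes == "excitatory"] <-
            expr[excShifted, classes == "excitatory"] * shiftEffect
        expr[inhShifted, classes == "inhibitory"] <-
            expr[inhShifted, classes == "inhibitory"] * shiftEffect
        list(expr = expr, excShifted = excShifted, inhShifted = inhShifted)
    })
    ann <- data.frame(neuron_class = classes, neuron_type = types,
                      row.names = types)
    exp <- PagExperiment(out$expr, ann, role = "neuron",
                         metadata = list(seed = seed))
    list(experiment = exp,
         truth = list(excShifted = out$excShifted,
                      inhShifted = out$inhShifted,
                      background = setdiff(genes, c(out$excShifted,
                                                    out$inhShifted))))
}

# Temporal programs on time-node index 1..Tn: a late rising logistic
# (module 1) and an early-prenatal decaying logistic (module 2). The two
# midpoints are deliberately offset (0.625*Tn vs 0.25*Tn) so the profiles
# are not exact mirrors: under an unsigned |cor| network mirrored profiles
# are maximally adjacent and indistinguishable.
.risingProfile <- function(t, Tn) stats::plogis(1.5 * 12 / Tn * (t - 0.625 * Tn))
.decayingProfile <- function(t, Tn) stats::plogis(-1.5 * 12 / Tn * (t - 0.25 * Tn))

#' Simulate a developmental region-by-stage expression matrix
#'
#' One sample per (brain region, time-node) grid cell, with a random
#' \code{missingFraction} of cells absent (dropped samples, not zeros),
#' emulating an incompletely sampled developmental atlas. Two planted
#' co-expression programs are embedded: module-1 genes share a rising
#' logistic temporal profile (low prenatal, high and stable postnatal) and
#' module-2 genes a decaying early-prenatal-high profile; all remaining
#' genes are unstructured noise. \code{amplitude = 0} removes all planted
#' correlation structure.
#'
#' @param nGenes number of genes.
#' @param module1Size,module2Size planted module sizes.
#' @param nRegions number of brain regions (default 16).
#' @param nTimepoints number of time-nodes (default 12; must be even, the
#'   first half is prenatal).
#' @param amplitude log2-scale swing of the planted temporal programs.
#' @param noiseSd per-sample log2-scale noise sd.
#' @param missingFraction fraction of region x time cells absent, in [0,1).
#' @param baseLogMean gene-baseline log2 mean expression.
#' @param seed integer RNG seed.
#' @return list with \code{experiment} (role "development") and \code{truth}
#'   (list: \code{module1}, \code{module2}, \code{background} — a partition
#'   of the genes).
#' @export
simulateDevelopmentMatrix <- function(nGenes, module1Size, module2Size,
                                      nRegions = 16L, nTimepoints = 12L,
                                      amplitude = 4, noiseSd = 0.5,
                                      missingFraction = 0.15,
                                      baseLogMean = 4, seed = 1L) {
    nGenes <- .checkCount(nGenes, "nGenes", 1L)
    module1Size <- .checkCount(module1Size, "module1Size")
    module2Size <- .checkCount(module2Size, "module2Size")
    nRegions <- .checkCount(nRegions, "nRegions", 1L)
    nTimepoints <- .checkCount(nTimepoints, "nTimepoints", 2L)
    if (nTimepoints %% 2L != 0L)
        stop("'nTimepoints' must be even (prenatal/postnatal halves)")
    if (module1Size + module2Size > nGenes)
        stop("'module1Size' + 'module2Size' must be <= 'nGenes'")
    if (amplitude < 0) stop("'amplitude' must be >= 0")
    if (noiseSd <= 0) stop("'noiseSd' must be positive")
    if (missingFraction < 0 || missingFraction >= 1)
        stop("'missingFraction' must be in [0, 1)")

    genes <- paste0("GENE", zeroPad(seq_len(nGenes), nGenes))
    regions <- paste0("region_", zeroPad(seq_len(nRegions), nRegions))
    grid <- expand.grid(region = regions, stage = seq_len(nTimepoints),
                        stringsAsFactors = FALSE)
    samples <- paste0(grid$region, "_T", zeroPad(grid$stage, nTimepoints))

    m1 <- genes[seq_len(module1Size)]
    m2 <- genes[module1Size + seq_len(module2Size)]
    bg <- setdiff(genes, c(m1, m2))
    profile <- matrix(0, nrow = nGenes, ncol = nrow(grid),
                      dimnames = list(genes, samples))
    profile[m1, ] <- rep(amplitude * .risingProfile(grid$stage, nTimepoints),
                         each = length(m1))
    profile[m2, ] <- rep(amplitude * .decayingProfile(grid$stage, nTimepoints),
                         each = length(m2))

    out <- withSeed(seed, {
        base <- stats::rnorm(nGenes, baseLogMean, 1)
        noise <- matrix(stats::rnorm(nGenes * nrow(grid), 0, noiseSd),
                        nrow = nGenes)
        keep <- sort(sample(nrow(grid),
                            round((1 - missingFraction) * nrow(grid))))
        list(expr = 2^(base + profile + noise), keep = keep)
    })
    expr <- out$expr[, out$keep, drop = FALSE]
    grid <- grid[out$keep, , drop = FALSE]
    ann <- data.frame(region = grid$region,
                      stage_index = grid$stage,
                      prenatal = as.integer(grid$stage <= nTimepoints / 2L),
                      row.names = colnames(expr))
    exp <- PagExperiment(expr, ann, role = "development",
                         metadata = list(seed = seed,
                                         nTimepoints = nTimepoints))
    list(experiment = exp,
         truth = list(module1 = m1, module2 = m2, background = bg))
}

#' Simulate per-gene age-at-onset patient records
#'
#' Draws \code{perGeneN} ages per gene around \code{m1Median} for module-1
#' genes, \code{m2Median} for module-2 genes, and the midpoint of the two
#' for unassigned/background genes (normal with sd \code{spreadSd}, floored
#' at 1 year so all ages are positive).
#'
#' @param moduleTruth either the \code{truth} list of
#'   \code{\link{simulateDevelopmentMatrix}} (elements \code{module1},
#'   \code{module2}, \code{background}) or a named character vector
#'   gene -> \code{"module1"|"module2"|"background"}.
#' @param perGeneN patient records per gene.
#' @param m1Median,m2Median central age at onset (years) per module.
#' @param spreadSd sd (years) of the per-patient draw.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{gene}, \code{aao_years}, one row
#'   per patient record.
#' @export
simulateAAO <- function(moduleTruth, perGeneN = 20L, m1Median = 40,
                        m2Median = 55, spreadSd = 10, seed = 1L) {
    perGeneN <- .checkCount(perGeneN, "perGeneN", 1L)
    if (m1Median <= 0 || m2Median <= 0 || spreadSd <= 0)
        stop("'m1Median', 'm2Median' and 'spreadSd' must be positive")
    if (is.list(moduleTruth)) {
        membership <- rep(c("module1", "module2", "background"),
                          c(length(moduleTruth$module1),
                            length(moduleTruth$module2),
                            length(moduleTruth$background)))
        names(membership) <- c(moduleTruth$module1, moduleTruth$module2,
                               moduleTruth$background)
    } else membership <- moduleTruth
    centers <- c(module1 = m1Median, module2 = m2Median,
                 background = (m1Median + m2Median) / 2)
    if (!all(membership %in% names(centers)))
        stop("module membership labels must be module1/module2/background")
    genes <- names(membership)
    withSeed(seed, {
        aao <- pmax(1, stats::rnorm(length(genes) * perGeneN,
                                    mean = rep(centers[membership],
                                               each = perGeneN),
                                    sd = spreadSd))
        data.frame(gene = rep(genes, each = perGeneN), aao_years = aao)
    })
}
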