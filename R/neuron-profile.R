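#' Log2 display normalization of mean expression values
#'
#' \code{log2(value + pseudocount)}. Used for reporting and heatmap scales
#' only: the rank-sum comparison is invariant under monotone transforms, so
#' the statistical results never depend on the pseudocount.
#'
#' @param value non-negative mean expression value(s).
#' @param pseudocount added before the log (default 1).
#' @return log2-transformed values.
#' @examples
#' normalizeLog2(7)   # 3
#' normalizeLog2(0)   # 0
#' @export
normalizeLog2 <- function(value, pseudocount = 1.0) {
    if (any(value < 0, na.rm = TRUE)) stop("expression values must be >= 0")
    log2(value + pseudocount)
}

#' Mann-Whitney / Wilcoxon rank-sum test
#'
#' Midrank tie handling throughout. The p-value is by exact enumeration of
#' all group labelings when \code{length(x) + length(y) <= 12} and the
#' pooled values are tie-free, otherwise by the normal approximation with
#' the tie-corrected variance and a 0.5 continuity correction. If every
#' pooled value is identical the test degenerates to \code{U = n1*n2/2},
#' \code{p = 1}.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param alternative \code{"two.sided"} (default), \code{"greater"}
#'   (x tends larger) or \code{"less"}.
#' @param exact force (\code{TRUE}/\code{FALSE}) or auto-select
#'   (\code{NULL}) the enumeration branch; enumeration with ties is refused.
#' @return list with \code{statistic} (U of group x), \code{p.value},
#'   \code{method} ("exact" or "normal_approx"), \code{alternative}.
#' @examples
#' rankSumTest(1:3, 4:6)$p.value   # 0.1 by enumeration of the 20 labelings
#' @export
rankSumTest <- function(x, y, alternative = c("two.sided", "greater", "less"),
                        exact = NULL) {
    alternative <- match.arg(alternative)
    x <- as.numeric(x); y <- as.numeric(y)
    if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
    if (anyNA(x) || anyNA(y)) stop("NA values are not allowed")
    nx <- length(x); ny <- length(y); N <- nx + ny
    pooled <- c(x, y)
    r <- rank(pooled)                      # midranks
    U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    hasTies <- anyDuplicated(pooled) > 0L
    if (is.null(exact)) exact <- (N <= 12L) && !hasTies
    if (exact && hasTies)
        stop("exact enumeration is only available for tie-free samples")

    if (exact) {
        sets <- utils::combn(N, nx)
        Uall <- colSums(matrix(r[sets], nrow = nx)) - nx * (nx + 1) / 2
        eps <- sqrt(.Machine$double.eps)
        p <- switch(alternative,
            two.sided = mean(abs(Uall - mu) >= abs(U - mu) - eps),
            greater   = mean(Uall >= U - eps),
            less      = mean(Uall <= U + eps))
        return(list(statistic = U, p.value = p, method = "exact",
                    alternative = alternative))
    }
    ties <- table(pooled)
    sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0)  # all pooled values identical
        return(list(statistic = U, p.value = 1, method = "normal_approx",
                    alternative = alternative))
    sigma <- sqrt(sigma2)
    cc <- 0.5  # continuity correction toward the mean
    p <- switch(alternative,
        two.sided = {
            z <- (abs(U - mu) - cc) / sigma
            min(1, 2 * stats::pnorm(max(z, 0), lower.tail = FALSE))
        },
        greater = stats::pnorm((U - mu - cc) / sigma, lower.tail = FALSE),
        less    = stats::pnorm((U - mu + cc) / sigma))
    list(statistic = U, p.value = min(1, max(p, 0)), method = "normal_approx",
         alternative = alternative)
}

#' Profile a gene set across inhibitory and excitatory neuron types
#'
#' For each gene of the set, compares its per-type mean expression across
#' the inhibitory types against the excitatory types with the two-sided
#' rank-sum test (non-neuronal types are excluded). When \code{p < alpha}
#' the direction label is assigned by comparing the class medians of the
#' per-type means (falling back to class means on an exact median tie;
#' still-equal degenerates to \code{no_difference}).
#'
#' @param x a \linkS4class{PagExperiment} with role \code{"neuron"}.
#' @param geneSet GeneSet / GeneCatalog / character vector; genes absent
#'   from the matrix are skipped and recorded in the metadata.
#' @param alpha raw-p classification level (default 0.05).
#' @param alternative sidedness of the rank-sum test.
#' @return \linkS4class{DataFrame}, one row per profiled gene: \code{gene},
#'   \code{n_inh}, \code{n_exc}, \code{U}, \code{p}, \code{p_bh},
#'   \code{direction} (\code{excitatory_higher} / \code{inhibitory_higher} /
#'   \code{no_difference}), \code{mean_inh_log2}, \code{mean_exc_log2}
#'   (display scale, \code{\link{normalizeLog2}}). Metadata holds the
#'   skipped symbols and alpha.
#' @export
profileNeuronTypes <- function(x, geneSet, alpha = 0.05,
                               alternative = "two.sided") {
    stopifnot(is(x, "PagExperiment"), sampleRole(x) == "neuron")
    symbols <- if (is(geneSet, "GeneCatalog")) pagGenes(geneSet)
               else if (is(geneSet, "GeneSet")) geneSymbols(geneSet)
               else toupper(as.character(geneSet))
    expr <- SummarizedExperiment::assay(x, "expr")
    cls <- SummarizedExperiment::colData(x)$neuron_class
    inh <- expr[, cls == "inhibitory", drop = FALSE]
    exc <- expr[, cls == "excitatory", drop = FALSE]
    if (ncol(inh) == 0L || ncol(exc) == 0L)
        stop("need >= 1 inhibitory and >= 1 excitatory neuron type")
    skipped <- setdiff(symbols, rownames(expr))
    if (length(skipped))
        warning(length(skipped), " gene(s) absent from the matrix skipped")
    genes <- intersect(symbols, rownames(expr))
    if (length(genes) == 0L) stop("no set genes present in the matrix")

    rows <- lapply(genes, function(g) {
        ts <- rankSumTest(inh[g, ], exc[g, ], alternative = alternative)
        dir <- "no_difference"
        if (ts$p.value < alpha) {
            mi <- stats::median(inh[g, ]); me <- stats::median(exc[g, ])
            if (me == mi) { mi <- mean(inh[g, ]); me <- mean(exc[g, ]) }
            if (me > mi) dir <- "excitatory_higher"
            else if (mi > me) dir <- "inhibitory_higher"
        }
        data.frame(gene = g, n_inh = ncol(inh), n_exc = ncol(exc),
                   U = ts$statistic, p = ts$p.value, direction = dir,
                   mean_inh_log2 = normalizeLog2(mean(inh[g, ])),
                   mean_exc_log2 = normalizeLog2(mean(exc[g, ])))
    })
    res <- S4Vectors::DataFrame(do.call(rbind, rows))
    res$p_bh <- stats::p.adjust(res$p, "BH")
    res <- res[, c("gene", "n_inh", "n_exc", "U", "p", "p_bh", "direction",
                   "mean_inh_log2", "mean_exc_log2")]
    S4Vectors::metadata(res) <- list(skipped = skipped, alpha = alpha,
                                     alternative = alternative)
    res
}

#' Summarize a neuron profile into the headline counts
#'
#' @param profile result of \code{\link{profileNeuronTypes}}.
#' @return list: \code{n_tested}, \code{n_diff}, \code{n_no_difference},
#'   \code{n_exc_higher}, \code{n_inh_higher}, and the two percentages of
#'   \code{n_diff} formatted to 2 decimals (\code{pct_exc_higher},
#'   \code{pct_inh_higher}, e.g. \code{"59.65\%"} for 34 of 57).
#' @export
neuronSummary <- function(profile) {
    nExc <- sum(profile$direction == "excitatory_higher")
    nInh <- sum(profile$direction == "inhibitory_higher")
    nDiff <- nExc + nInh
    list(n_tested = nrow(profile),
         n_diff = nDiff,
         n_no_difference = nrow(profile) - nDiff,
         n_exc_higher = nExc,
         n_inh_higher = nInh,
         pct_exc_higher = if (nDiff > 0) formatPct(nExc, nDiff) else NA_character_,
         pct_inh_higher = if (nDiff > 0) formatPct(nInh, nDiff) else NA_character_)
}
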