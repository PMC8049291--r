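#' Call each gene's preferential expression tissues
#'
#' For every gene the tissues are ranked by decreasing mean expression; the
#' top \code{ceiling(topFraction * T)} tissues are candidate-preferential
#' (competition/"min" ranking on exact expression ties, then a lexicographic
#' tissue-label tie-break so the call is deterministic), and a tissue is
#' preferential iff it is a candidate AND the gene is expressed there
#' (expression >= \code{expressedThreshold}, the conventional RPKM-1 cut).
#' A gene expressed nowhere gets an empty preferential set.
#'
#' The candidate ranking depends only on the ordering of a gene's expression
#' values, so it is invariant under any strictly monotone transform.
#'
#' @param x a \linkS4class{PagExperiment} with role \code{"tissue"}, or a
#'   genes x tissues matrix.
#' @param topFraction fraction of tissues that are candidate-preferential,
#'   in (0, 1] (default 0.5).
#' @param expressedThreshold linear-scale expression floor for "expressed"
#'   (default 1).
#' @return logical genes x tissues matrix: TRUE where the tissue is
#'   preferential for the gene; attribute \code{"expressed"} holds the
#'   analogous expressed-tissue indicator.
#' @examples
#' m <- rbind(g1 = c(A = 10, B = 5, C = 2, D = 0.5))
#' callPreferentialTissues(m)["g1", ]   # A and B
#' @export
callPreferentialTissues <- function(x, topFraction = 0.5,
                                    expressedThreshold = 1.0) {
    expr <- if (is(x, "PagExperiment")) {
        stopifnot(sampleRole(x) == "tissue")
        SummarizedExperiment::assay(x, "expr")
    } else as.matrix(x)
    if (ncol(expr) < 2L) stop("need >= 2 tissues")
    if (topFraction <= 0 || topFraction > 1)
        stop("'topFraction' must be in (0, 1]")
    m <- ceiling(topFraction * ncol(expr))
    tissueOrder <- order(colnames(expr))  # lexicographic tie-break
    candidate <- matrix(FALSE, nrow(expr), ncol(expr), dimnames = dimnames(expr))
    for (i in seq_len(nrow(expr))) {
        v <- expr[i, ]
        ord <- order(-v[tissueOrder])     # stable: ties fall back to label order
        candidate[i, tissueOrder[ord[seq_len(m)]]] <- TRUE
    }
    expressed <- !is.na(expr) & expr >= expressedThreshold
    pref <- candidate & expressed
    attr(pref, "expressed") <- expressed
    pref
}

# One-sided (enrichment) Fisher exact p for the 2x2 table
# [k, K-k; n-k, N-K-n+k]: P(X >= k), X ~ Hypergeom(N, K, n).
.fisherGreater <- function(k, K, n, N) {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Per-tissue enrichment of a gene set in preferential-expression calls
#'
#' For each tissue, tests whether the gene set's members are over-represented
#' among the genes calling that tissue preferential, with a one-sided Fisher
#' exact test on the 2x2 table (set x preferential) against the background
#' universe. The universe defaults to all genes of the expression table that
#' are expressed (>= \code{expressedThreshold}) in at least one tissue; set
#' genes absent from the universe are dropped with a warning.
#'
#' @param x a \linkS4class{PagExperiment} (role "tissue") or genes x tissues
#'   matrix.
#' @param geneSet a \linkS4class{GeneSet}, \linkS4class{GeneCatalog} (its
#'   PAG union is used) or character vector of symbols.
#' @param topFraction,expressedThreshold passed to
#'   \code{\link{callPreferentialTissues}}.
#' @param alternative \code{"greater"} (default, enrichment) or
#'   \code{"two.sided"}.
#' @param alpha raw-p significance cut for the \code{significant} flag
#'   (default 0.01).
#' @return a \linkS4class{DataFrame} sorted by p, one row per tissue:
#'   \code{tissue}, contingency counts \code{k} (set genes preferential
#'   here), \code{K} (set genes in universe), \code{n} (universe genes
#'   preferential here), \code{N} (universe size), \code{odds_ratio},
#'   \code{p}, \code{p_bh} (Benjamini-Hochberg across tissues),
#'   \code{significant} (raw p < alpha). Metadata records dropped symbols.
#' @export
enrichTissues <- function(x, geneSet, topFraction = 0.5,
                          expressedThreshold = 1.0,
                          alternative = c("greater", "two.sided"),
                          alpha = 0.01) {
    alternative <- match.arg(alternative)
    symbols <- if (is(geneSet, "GeneCatalog")) pagGenes(geneSet)
               else if (is(geneSet, "GeneSet")) geneSymbols(geneSet)
               else toupper(as.character(geneSet))
    if (length(symbols) == 0L) stop("empty gene set")
    pref <- callPreferentialTissues(x, topFraction, expressedThreshold)
    expressed <- attr(pref, "expressed")
    universe <- rownames(pref)[rowSums(expressed) > 0]
    if (length(universe) == 0L) stop("empty universe: no expressed genes")
    dropped <- setdiff(symbols, universe)
    if (length(dropped))
        warning(length(dropped), " set gene(s) absent from the universe ",
                "and dropped: ", paste(utils::head(dropped, 10), collapse = ", "),
                if (length(dropped) > 10) ", ...")
    inSet <- intersect(symbols, universe)
    if (length(inSet) == 0L) stop("no set genes present in the universe")

    pref <- pref[universe, , drop = FALSE]
    N <- length(universe)
    K <- length(inSet)
    k <- colSums(pref[inSet, , drop = FALSE])
    n <- colSums(pref)
    p <- if (alternative == "greater") {
        .fisherGreater(k, K, n, N)
    } else {
        vapply(seq_along(k), function(j) {
            tab <- matrix(c(k[j], K - k[j], n[j] - k[j], N - K - n[j] + k[j]),
                          2L)
            stats::fisher.test(tab)$p.value
        }, numeric(1))
    }
    or <- (k * (N - K - n + k)) / pmax(K - k, .Machine$double.eps) /
        pmax(n - k, .Machine$double.eps)
    res <- S4Vectors::DataFrame(tissue = colnames(pref), k = as.integer(k),
                                K = K, n = as.integer(n), N = N,
                                odds_ratio = or, p = p,
                                p_bh = stats::p.adjust(p, "BH"),
                                significant = p < alpha)
    res <- res[order(res$p, res$tissue), ]
    rownames(res) <- NULL
    S4Vectors::metadata(res) <- list(dropped = dropped, alpha = alpha,
                                     alternative = alternative)
    res
}
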