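#' Per-gene log2 fold-change normalization against the gene mean
#'
#' \code{log2((value + eps) / (geneMean + eps))} with the gene mean taken
#' over the gene's non-missing samples; \code{eps} guards zeros. The
#' transform is invariant under per-gene rescaling (doubling every raw value
#' of a gene leaves its normalized profile unchanged) and a constant gene
#' maps to all zeros. Genes whose mean is 0 (all-zero genes) are dropped
#' with a warning.
#'
#' @param x \linkS4class{PagExperiment} (any role) or genes x samples
#'   matrix of non-negative values.
#' @param eps pseudocount (default 1e-3).
#' @return matrix of normalized values, same shape minus dropped genes;
#'   attribute \code{"dropped"} lists dropped gene symbols.
#' @export
normalizeFoldChange <- function(x, eps = 1e-3) {
    expr <- if (is(x, "PagExperiment")) SummarizedExperiment::assay(x, "expr")
            else as.matrix(x)
    if (any(expr < 0, na.rm = TRUE)) stop("expression values must be >= 0")
    gm <- rowMeans(expr, na.rm = TRUE)
    bad <- !is.finite(gm) | gm <= 0
    if (any(bad)) {
        warning(sum(bad), " gene(s) with zero mean expression dropped: ",
                paste(utils::head(rownames(expr)[bad], 10), collapse = ", "))
        expr <- expr[!bad, , drop = FALSE]
        gm <- gm[!bad]
    }
    norm <- log2((expr + eps) / (gm + eps))
    attr(norm, "dropped") <- rownames(x)[bad]
    norm
}

#' Soft-thresholded adjacency and topological overlap matrix
#'
#' Builds the unsigned weighted co-expression network: adjacency
#' \code{a_ij = |cor(i, j)|^power} (Pearson, pairwise-complete when samples
#' are missing; pairs sharing fewer than \code{minShared} samples get
#' correlation 0 and are counted in the metadata), unit diagonal; and the
#' unsigned topological overlap
#' \deqn{TOM_{ij} = (\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}) /
#'       (\min(k_i, k_j) + 1 - a_{ij}),}
#' \eqn{k_i = \sum_{u \ne i} a_{iu}}, \eqn{TOM_{ii} = 1}. Zero-variance
#' genes are dropped before correlation with a warning.
#'
#' @param normMatrix genes x samples matrix of normalized expression (see
#'   \code{\link{normalizeFoldChange}}).
#' @param power soft-threshold exponent beta (default 7).
#' @param minShared minimum shared non-missing samples per gene pair
#'   (default 4).
#' @return list: \code{adjacency}, \code{tom} (both genes x genes, symmetric,
#'   in [0,1], unit diagonal), \code{nLowOverlapPairs}.
#' @export
buildNetwork <- function(normMatrix, power = 7, minShared = 4L) {
    if (power <= 0) stop("'power' must be positive")
    X <- as.matrix(normMatrix)
    if (nrow(X) < 3L) stop("need >= 3 genes")
    if (ncol(X) < 4L) stop("need >= 4 samples")
    v <- apply(X, 1L, stats::var, na.rm = TRUE)
    bad <- !is.finite(v) | v == 0
    if (any(bad)) {
        warning(sum(bad), " zero-variance gene(s) dropped before correlation")
        X <- X[!bad, , drop = FALSE]
        if (nrow(X) < 3L) stop("fewer than 3 genes left after dropping")
    }
    cc <- suppressWarnings(stats::cor(t(X), use = "pairwise.complete.obs"))
    shared <- tcrossprod(!is.na(X))
    low <- shared < minShared
    diag(low) <- FALSE
    cc[low | is.na(cc)] <- 0
    a <- abs(cc)^power
    diag(a) <- 1
    k <- rowSums(a) - 1
    # (a %*% a)_ij = sum_{u != i,j} a_iu a_uj + 2 a_ij for unit diagonal,
    # so the TOM numerator sum_{u != i,j} a_iu a_uj + a_ij is (a%*%a)_ij - a_ij
    kmin <- outer(k, k, pmin)
    tom <- (a %*% a - a) / (kmin + 1 - a)
    diag(tom) <- 1
    tom <- (tom + t(tom)) / 2  # symmetrize away numerical asymmetry
    list(adjacency = a, tom = tom,
         nLowOverlapPairs = sum(low & upper.tri(low)))
}

#' Detect co-expression modules by static tree cut of the TOM dendrogram
#'
#' Average-linkage hierarchical clustering on dissimilarity \code{1 - TOM},
#' cut at a fixed height; clusters smaller than \code{minModuleSize} become
#' unassigned (label 0). Modules are relabeled by decreasing size (ties by
#' first member symbol), so module 1 is always the largest. Deterministic
#' given its input; finding zero modules is a valid outcome.
#'
#' @param tom symmetric TOM in [0,1] with unit diagonal (or the list from
#'   \code{\link{buildNetwork}}).
#' @param cutHeight static cut height on the 1-TOM scale, in (0,1]
#'   (default 0.85).
#' @param minModuleSize minimum retained cluster size (default 10).
#' @return a \linkS4class{ModuleAssignment} (labels only; see
#'   \code{\link{summarizeModules}} for eigengenes and profiles).
#' @export
detectModules <- function(tom, cutHeight = 0.85, minModuleSize = 10L) {
    if (is.list(tom)) tom <- tom$tom
    if (!isSymmetric(unname(tom), tol = 1e-8))
        stop("TOM must be symmetric")
    if (any(tom < -1e-8 | tom > 1 + 1e-8) || any(abs(diag(tom) - 1) > 1e-8))
        stop("TOM must lie in [0,1] with unit diagonal")
    if (cutHeight <= 0 || cutHeight > 1)
        stop("'cutHeight' must be in (0, 1]")
    minModuleSize <- .checkCount(minModuleSize, "minModuleSize", 2L)
    genes <- rownames(tom)
    if (is.null(genes)) genes <- paste0("g", seq_len(nrow(tom)))
    hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
    raw <- stats::cutree(hc, h = cutHeight)
    sizes <- table(raw)
    keep <- as.integer(names(sizes)[sizes >= minModuleSize])
    labels <- integer(length(raw))
    names(labels) <- genes
    if (length(keep)) {
        firstMember <- vapply(keep, function(cl) sort(genes[raw == cl])[1L], "")
        ord <- keep[order(-as.integer(sizes[as.character(keep)]), firstMember)]
        for (j in seq_along(ord)) labels[raw == ord[j]] <- j
    }
    new("ModuleAssignment", labels = labels,
        eigengenes = matrix(numeric(0), nrow = 0, ncol = 0),
        temporalProfiles = matrix(numeric(0), nrow = 0, ncol = 0),
        spatialProfiles = matrix(numeric(0), nrow = 0, ncol = 0),
        temporalClass = character(0),
        params = list(cutHeight = cutHeight, minModuleSize = minModuleSize))
}

#' Summarize detected modules over time-nodes and brain regions
#'
#' For each module: the eigengene (first principal component of the
#' module's row-standardized normalized expression, unit norm, sign aligned
#' to the module mean profile), the temporal profile (mean normalized
#' expression per developmental time-node), the spatial profile (mean per
#' region), and the temporal class: \code{postnatal_high} if the postnatal
#' time-node mean exceeds the prenatal mean by more than \code{margin}
#' log2 units, \code{prenatal_high} for the reverse, else
#' \code{indeterminate}.
#'
#' @param assignment \linkS4class{ModuleAssignment} from
#'   \code{\link{detectModules}}.
#' @param normMatrix genes x samples normalized matrix the modules were
#'   detected on.
#' @param x the \linkS4class{PagExperiment} (role "development") carrying
#'   the sample annotation (region, stage_index, prenatal).
#' @param margin temporal-class margin in log2 units (default 0.1).
#' @return the assignment with \code{eigengenes}, \code{temporalProfiles},
#'   \code{spatialProfiles} and \code{temporalClass} filled in.
#' @export
summarizeModules <- function(assignment, normMatrix, x, margin = 0.1) {
    stopifnot(is(assignment, "ModuleAssignment"),
              is(x, "PagExperiment"), sampleRole(x) == "development")
    cd <- SummarizedExperiment::colData(x)
    samples <- colnames(normMatrix)
    if (!all(samples %in% colnames(x)))
        stop("normalized matrix samples missing from the experiment")
    cd <- cd[samples, , drop = FALSE]
    stages <- sort(unique(as.integer(cd$stage_index)))
    regions <- sort(unique(cd$region))
    labels <- assignment@labels
    k <- length(moduleSizesInternal(labels))
    if (k == 0L) return(assignment)
    eg <- matrix(NA_real_, length(samples), k,
                 dimnames = list(samples, paste0("M", seq_len(k))))
    tprof <- matrix(NA_real_, k, length(stages),
                    dimnames = list(paste0("M", seq_len(k)),
                                    paste0("node_", stages)))
    sprof <- matrix(NA_real_, k, length(regions),
                    dimnames = list(paste0("M", seq_len(k)), regions))
    tclass <- character(k)
    halfIdx <- as.integer(cd$prenatal) == 1L
    for (m in seq_len(k)) {
        members <- names(labels)[labels == m]
        if (!all(members %in% rownames(normMatrix)))
            stop("module ", m, " members missing from the normalized matrix")
        M <- normMatrix[members, , drop = FALSE]
        meanProfile <- colMeans(M, na.rm = TRUE)
        Z <- t(scale(t(M)))                     # row-standardize
        Z[!is.finite(Z)] <- 0                   # constant genes / missing cells
        sv <- svd(Z, nu = 0, nv = 1)
        e <- sv$v[, 1L]
        if (stats::cor(e, meanProfile) < 0) e <- -e
        eg[, m] <- e
        tprof[m, ] <- vapply(stages, function(s)
            mean(M[, cd$stage_index == s, drop = FALSE], na.rm = TRUE),
            numeric(1))
        sprof[m, ] <- vapply(regions, function(r)
            mean(M[, cd$region == r, drop = FALSE], na.rm = TRUE), numeric(1))
        post <- mean(M[, !halfIdx, drop = FALSE], na.rm = TRUE)
        pre <- mean(M[, halfIdx, drop = FALSE], na.rm = TRUE)
        tclass[m] <- if (post - pre > margin) "postnatal_high"
                     else if (pre - post > margin) "prenatal_high"
                     else "indeterminate"
    }
    initialize(assignment, eigengenes = eg, temporalProfiles = tprof,
               spatialProfiles = sprof, temporalClass = tclass,
               params = c(assignment@params, list(margin = margin)))
}

#' @rdname ModuleAssignment-class
#' @param x a ModuleAssignment.
#' @export
setMethod("moduleLabels", "ModuleAssignment", function(x) x@labels)

#' @describeIn ModuleAssignment-class sizes of the detected modules
#'   (named "1", "2", ...; unassigned genes excluded).
#' @export
setMethod("moduleSizes", "ModuleAssignment",
    function(x) moduleSizesInternal(x@labels))

#' @rdname ModuleAssignment-class
#' @export
setMethod("eigengenes", "ModuleAssignment", function(x) x@eigengenes)

#' @rdname ModuleAssignment-class
#' @export
setMethod("temporalClass", "ModuleAssignment", function(x) x@temporalClass)

#' @rdname ModuleAssignment-class
#' @export
setMethod("geneSymbols", "ModuleAssignment", function(x) names(x@labels))

setMethod("show", "ModuleAssignment", function(object) {
    sz <- moduleSizes(object)
    cat("ModuleAssignment:", length(sz), "module(s),",
        sum(object@labels == 0L), "unassigned of", length(object@labels),
        "genes\n")
    for (m in seq_along(sz))
        cat(sprintf("  M%d: %d genes%s\n", m, sz[m],
                    if (length(object@temporalClass) >= m)
                        paste0(" (", object@temporalClass[m], ")") else ""))
})
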