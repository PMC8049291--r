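#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' GeneSet: a named, deduplicated collection of gene symbols
#'
#' Gene symbols are stored uppercase, in first-seen order, with duplicates
#' removed. Provenance is free text describing where the list came from.
#'
#' @slot name single character label for the set.
#' @slot symbols character vector of unique uppercase gene symbols.
#' @slot provenance free-text provenance label.
#'
#' @examples
#' gs <- GeneSet("demo", c("snca", "PRKN"))
#' geneSymbols(gs)
#' @exportClass GeneSet
setClass("GeneSet",
    representation(name = "character", symbols = "character",
                   provenance = "character"))

setValidity("GeneSet", function(object) {
    msg <- NULL
    if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    if (length(object@symbols) == 0L)
        msg <- c(msg, "'symbols' must be non-empty")
    if (anyDuplicated(object@symbols))
        msg <- c(msg, "'symbols' must be unique after normalization")
    if (any(!nzchar(object@symbols)) || anyNA(object@symbols))
        msg <- c(msg, "'symbols' must be non-empty strings")
    if (!identical(object@symbols, toupper(object@symbols)))
        msg <- c(msg, "'symbols' must be uppercase")
    if (is.null(msg)) TRUE else msg
})

#' GeneCatalog: the disease-causing and risk gene sets of a study
#'
#' Holds the two curated \linkS4class{GeneSet}s (causing and risk) and exposes
#' their union (the analysis gene set, "PAGs") and intersection through
#' accessors. The union is deduplicated by exact symbol, so
#' \code{length(pagGenes(x)) == length(causing) + length(risk) - length(overlap)}.
#'
#' @slot causing GeneSet of disease-causing genes.
#' @slot risk GeneSet of risk genes.
#' @exportClass GeneCatalog
setClass("GeneCatalog",
    representation(causing = "GeneSet", risk = "GeneSet"))

#' PagExperiment: an annotated expression matrix for one analysis role
#'
#' A thin \linkS4class{SummarizedExperiment} subclass carrying a genes x
#' samples matrix of non-negative, linear-scale (RPKM-like) expression values
#' in the \code{"expr"} assay, plus the sample annotation the stage needs:
#' \describe{
#'   \item{role \code{"tissue"}}{colData column \code{tissue} (unique labels);
#'     samples are per-tissue mean expression profiles.}
#'   \item{role \code{"neuron"}}{colData columns \code{neuron_class}
#'     (\code{inhibitory}/\code{excitatory}/\code{non_neuronal}) and
#'     \code{neuron_type}; samples are per-neuron-type means.}
#'   \item{role \code{"development"}}{colData columns \code{region},
#'     \code{stage_index} (1..n_timepoints) and \code{prenatal} (0/1,
#'     consistent with stage_index: first half prenatal).}
#' }
#' Missing cells of an incomplete sampling grid are \code{NA} in the assay.
#'
#' @slot role one of "tissue", "neuron", "development".
#' @exportClass PagExperiment
setClass("PagExperiment",
    contains = "SummarizedExperiment",
    representation(role = "character"))

.PAG_ROLES <- c("tissue", "neuron", "development")
.NEURON_CLASSES <- c("inhibitory", "excitatory", "non_neuronal")

setValidity("PagExperiment", function(object) {
    msg <- NULL
    if (length(object@role) != 1L || !object@role %in% .PAG_ROLES)
        return(sprintf("'role' must be one of %s",
                       paste(.PAG_ROLES, collapse = ", ")))
    if (!"expr" %in% SummarizedExperiment::assayNames(object))
        return("assay 'expr' is required")
    x <- SummarizedExperiment::assay(object, "expr")
    if (any(x < 0, na.rm = TRUE))
        msg <- c(msg, "expression values must be non-negative")
    if (is.null(rownames(object)))
        msg <- c(msg, "gene symbols (rownames) are required")
    cd <- SummarizedExperiment::colData(object)
    if (object@role == "tissue") {
        if (!"tissue" %in% colnames(cd))
            msg <- c(msg, "role 'tissue' needs colData column 'tissue'")
        else if (anyDuplicated(cd$tissue))
            msg <- c(msg, "tissue labels must be unique")
    } else if (object@role == "neuron") {
        if (!all(c("neuron_class", "neuron_type") %in% colnames(cd)))
            msg <- c(msg, "role 'neuron' needs colData columns 'neuron_class' and 'neuron_type'")
        else if (!all(cd$neuron_class %in% .NEURON_CLASSES))
            msg <- c(msg, sprintf("'neuron_class' values must be in {%s}",
                                  paste(.NEURON_CLASSES, collapse = ", ")))
    } else {
        need <- c("region", "stage_index", "prenatal")
        if (!all(need %in% colnames(cd)))
            msg <- c(msg, "role 'development' needs colData columns 'region', 'stage_index', 'prenatal'")
        else {
            si <- as.integer(cd$stage_index)
            half <- max(si) / 2
            if (!all(cd$prenatal %in% c(0L, 1L)))
                msg <- c(msg, "'prenatal' must be 0/1")
            else if (!all((si <= half) == (cd$prenatal == 1L)))
                msg <- c(msg, "'prenatal' flag inconsistent with 'stage_index' (first half must be prenatal)")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' ModuleAssignment: detected co-expression modules and their summaries
#'
#' Result of \code{\link{detectModules}} (labels only) optionally augmented by
#' \code{\link{summarizeModules}} (eigengenes, temporal/spatial profiles and
#' prenatal/postnatal classification).
#'
#' @slot labels named integer vector, one per gene; 0 means unassigned,
#'   modules are numbered 1..k by decreasing size.
#' @slot eigengenes samples x modules matrix of unit-norm module eigengenes
#'   (first principal components), or a 0-column matrix before summarization.
#' @slot temporalProfiles modules x time-nodes matrix of mean normalized
#'   expression per developmental time-node.
#' @slot spatialProfiles modules x regions matrix of mean normalized
#'   expression per brain region.
#' @slot temporalClass character per module:
#'   \code{postnatal_high}, \code{prenatal_high} or \code{indeterminate}.
#' @slot params list of the network/clustering parameters used.
#' @exportClass ModuleAssignment
setClass("ModuleAssignment",
    representation(labels = "integer", eigengenes = "matrix",
                   temporalProfiles = "matrix", spatialProfiles = "matrix",
                   temporalClass = "character", params = "list"))

setValidity("ModuleAssignment", function(object) {
    msg <- NULL
    if (is.null(names(object@labels)))
        msg <- c(msg, "'labels' must be named by gene symbol")
    k <- length(moduleSizesInternal(object@labels))
    if (length(object@labels) && k > 0) {
        lev <- sort(unique(object@labels[object@labels > 0L]))
        if (!identical(lev, seq_len(k)))
            msg <- c(msg, "module labels must be consecutive 1..k")
    }
    if (length(object@temporalClass) &&
        !all(object@temporalClass %in%
             c("postnatal_high", "prenatal_high", "indeterminate")))
        msg <- c(msg, "invalid temporal class label")
    if (is.null(msg)) TRUE else msg
})

moduleSizesInternal <- function(labels) {
    tab <- table(labels[labels > 0L])
    structure(as.integer(tab), names = names(tab))
}
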