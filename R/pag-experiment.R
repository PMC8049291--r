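#' Construct a PagExperiment
#'
#' @param expr genes x samples numeric matrix (non-negative, linear scale;
#'   NA marks absent samples of an incomplete grid).
#' @param colData data.frame / DataFrame of per-sample annotation (see
#'   \linkS4class{PagExperiment} for the columns each role requires).
#' @param role one of \code{"tissue"}, \code{"neuron"}, \code{"development"}.
#' @param metadata optional list stored in the object metadata (e.g. the
#'   simulation seed).
#' @return a \linkS4class{PagExperiment}.
#' @export
PagExperiment <- function(expr, colData, role, metadata = list()) {
    role <- match.arg(role, .PAG_ROLES)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = as.matrix(expr)),
        colData = S4Vectors::DataFrame(colData),
        metadata = metadata)
    new("PagExperiment", se, role = role)
}

#' @rdname PagExperiment
#' @param x a PagExperiment.
#' @export
setMethod("sampleRole", "PagExperiment", function(x) x@role)

#' @rdname PagExperiment
#' @export
setMethod("geneSymbols", "PagExperiment", function(x) rownames(x))

setMethod("show", "PagExperiment", function(object) {
    cat("PagExperiment (role='", object@role, "'): ", nrow(object),
        " genes x ", ncol(object), " samples\n", sep = "")
    callNextMethod()
})

#' Read / write an expression matrix with its sample annotation
#'
#' The matrix TSV has a first column \code{gene_id} followed by one column
#' per sample; the annotation TSV has \code{sample_id}, \code{role} and the
#' role-specific columns. Absent grid cells are encoded as \code{NA}.
#'
#' @param matrixPath,annotPath TSV paths.
#' @return \code{readExpressionTSV}: a \linkS4class{PagExperiment}.
#' @export
readExpressionTSV <- function(matrixPath, annotPath) {
    mat <- utils::read.delim(matrixPath, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (colnames(mat)[1L] != "gene_id")
        stop("first column of ", matrixPath, " must be 'gene_id'")
    expr <- as.matrix(mat[, -1L, drop = FALSE])
    rownames(expr) <- mat$gene_id
    ann <- utils::read.delim(annotPath, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "role") %in% colnames(ann)))
        stop("annotation TSV needs 'sample_id' and 'role' columns")
    role <- unique(ann$role)
    if (length(role) != 1L)
        stop("annotation mixes roles: ", paste(role, collapse = ", "))
    if (!setequal(colnames(expr), ann$sample_id))
        stop("matrix columns and annotation sample_ids disagree")
    ann <- ann[match(colnames(expr), ann$sample_id), , drop = FALSE]
    rownames(ann) <- ann$sample_id
    PagExperiment(expr, ann[setdiff(colnames(ann), "role")], role)
}

#' @rdname readExpressionTSV
#' @param x a \linkS4class{PagExperiment} to write.
#' @return \code{writeExpressionTSV}: the matrix path, invisibly.
#' @export
writeExpressionTSV <- function(x, matrixPath, annotPath) {
    stopifnot(is(x, "PagExperiment"))
    expr <- SummarizedExperiment::assay(x, "expr")
    df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
    utils::write.table(df, matrixPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    ann <- cbind(sample_id = colnames(expr), role = x@role, cd)
    utils::write.table(ann, annotPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(matrixPath)
}

#' Read an age-at-onset record table
#'
#' One row per patient record: columns \code{gene}, \code{aao_years}.
#'
#' @param path TSV path.
#' @return data.frame with uppercase \code{gene} and numeric positive
#'   \code{aao_years}.
#' @export
readAAOTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene", "aao_years") %in% colnames(df)))
        stop("AAO TSV needs columns 'gene' and 'aao_years'")
    df$gene <- toupper(trimws(df$gene))
    df$aao_years <- as.numeric(df$aao_years)
    if (any(!is.finite(df$aao_years)) || any(df$aao_years <= 0))
        stop("AAO values must be positive and finite")
    df
}
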