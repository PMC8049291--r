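#' @rdname GeneSet-class
#' @param x a GeneSet, GeneCatalog, PagExperiment or ModuleAssignment.
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname GeneCatalog-class
#' @export
setGeneric("causingGenes", function(x) standardGeneric("causingGenes"))

#' @rdname GeneCatalog-class
#' @export
setGeneric("riskGenes", function(x) standardGeneric("riskGenes"))

#' @rdname GeneCatalog-class
#' @export
setGeneric("pagGenes", function(x) standardGeneric("pagGenes"))

#' @rdname GeneCatalog-class
#' @export
setGeneric("overlapGenes", function(x) standardGeneric("overlapGenes"))

#' @rdname PagExperiment
#' @export
setGeneric("sampleRole", function(x) standardGeneric("sampleRole"))

#' @rdname ModuleAssignment-class
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @rdname ModuleAssignment-class
#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))

#' @rdname ModuleAssignment-class
#' @export
setGeneric("eigengenes", function(x) standardGeneric("eigengenes"))

#' @rdname ModuleAssignment-class
#' @export
setGeneric("temporalClass", function(x) standardGeneric("temporalClass"))
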