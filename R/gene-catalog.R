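#' Construct a GeneSet
#'
#' Symbols are trimmed, uppercased and deduplicated (first occurrence kept,
#' order preserved); dropped duplicates raise a warning, never an error.
#'
#' @param name label for the set.
#' @param symbols character vector of gene symbols.
#' @param provenance free-text provenance.
#' @return a \linkS4class{GeneSet}.
#' @examples
#' GeneSet("demo", c("snca", "SNCA", "PRKN"))  # one duplicate dropped
#' @export
GeneSet <- function(name, symbols, provenance = NA_character_) {
    symbols <- toupper(trimws(as.character(symbols)))
    symbols <- symbols[nzchar(symbols)]
    if (length(symbols) == 0L)
        stop("gene set '", name, "' is empty")
    dup <- duplicated(symbols)
    if (any(dup))
        warning(sum(dup), " duplicate symbol(s) dropped from '", name, "': ",
                paste(unique(symbols[dup]), collapse = ", "))
    new("GeneSet", name = as.character(name), symbols = symbols[!dup],
        provenance = as.character(provenance))
}

#' Read a one-symbol-per-line gene list (or a GMT row)
#'
#' Plain-text lists have one symbol per line; a GMT file (extension
#' \code{.gmt}) contributes the symbols of its first row, whose first two
#' fields are the set name and description.
#'
#' @param path file path.
#' @param name set label; defaults to the file name without extension.
#' @return a \linkS4class{GeneSet}.
#' @export
readGeneList <- function(path, name = NULL) {
    if (!file.exists(path)) stop("gene list not found: ", path)
    if (is.null(name))
        name <- sub("\\.[^.]*$", "", basename(path))
    lines <- readLines(path, warn = FALSE)
    if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
        fields <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
        if (length(fields) < 3L) stop("malformed GMT row in ", path)
        name <- fields[1L]
        syms <- fields[-(1:2)]
    } else {
        syms <- lines
    }
    syms <- syms[nzchar(trimws(syms))]
    if (length(syms) == 0L) stop("empty gene list: ", path)
    GeneSet(name, syms, provenance = path)
}

#' Build a GeneCatalog from the causing and risk sets
#'
#' @param causing,risk \linkS4class{GeneSet}s.
#' @return a \linkS4class{GeneCatalog}; \code{pagGenes()} gives the exact
#'   symbol union, \code{overlapGenes()} the intersection.
#' @examples
#' cat <- GeneCatalog(GeneSet("causing", c("SNCA", "PRKN")),
#'                    GeneSet("risk", c("SNCA", "GCH1")))
#' pagGenes(cat)
#' @export
GeneCatalog <- function(causing, risk) {
    stopifnot(is(causing, "GeneSet"), is(risk, "GeneSet"))
    new("GeneCatalog", causing = causing, risk = risk)
}

#' @rdname GeneSet-class
#' @export
setMethod("geneSymbols", "GeneSet", function(x) x@symbols)

#' @describeIn GeneSet-class number of symbols in the set.
#' @export
setMethod("length", "GeneSet", function(x) length(x@symbols))

setMethod("show", "GeneSet", function(object) {
    cat("GeneSet '", object@name, "': ", length(object@symbols),
        " symbols\n", sep = "")
    head_syms <- utils::head(object@symbols, 6L)
    cat("  ", paste(head_syms, collapse = ", "),
        if (length(object@symbols) > 6L) ", ..." else "", "\n", sep = "")
})

#' @rdname GeneCatalog-class
#' @export
setMethod("causingGenes", "GeneCatalog", function(x) x@causing@symbols)

#' @rdname GeneCatalog-class
#' @export
setMethod("riskGenes", "GeneCatalog", function(x) x@risk@symbols)

#' @describeIn GeneCatalog-class deduplicated union of causing and risk
#'   symbols (the PAG set), in first-seen order.
#' @export
setMethod("pagGenes", "GeneCatalog",
    function(x) unique(c(x@causing@symbols, x@risk@symbols)))

#' @describeIn GeneCatalog-class symbols present in both sets.
#' @export
setMethod("overlapGenes", "GeneCatalog",
    function(x) intersect(x@causing@symbols, x@risk@symbols))

#' @rdname GeneCatalog-class
#' @export
setMethod("geneSymbols", "GeneCatalog", function(x) pagGenes(x))

setMethod("show", "GeneCatalog", function(object) {
    cat("GeneCatalog:", length(object@causing), "causing +",
        length(object@risk), "risk genes;",
        length(overlapGenes(object)), "shared;",
        length(pagGenes(object)), "total\n")
    if (length(overlapGenes(object)))
        cat("  shared:", paste(overlapGenes(object), collapse = ", "), "\n")
})

#' Serialize / deserialize a GeneCatalog as TSV
#'
#' Columns \code{symbol}, \code{in_causing}, \code{in_risk} (0/1). The round
#' trip is lossless up to set names and provenance.
#'
#' @param catalog a \linkS4class{GeneCatalog}.
#' @param path output (input) TSV path.
#' @return \code{writeCatalogTSV}: the path, invisibly.
#' @export
writeCatalogTSV <- function(catalog, path) {
    syms <- pagGenes(catalog)
    df <- data.frame(symbol = syms,
                     in_causing = as.integer(syms %in% causingGenes(catalog)),
                     in_risk = as.integer(syms %in% riskGenes(catalog)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCatalogTSV
#' @export
readCatalogTSV <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("symbol", "in_causing", "in_risk")
    if (!all(need %in% colnames(df)))
        stop("catalog TSV needs columns: ", paste(need, collapse = ", "))
    GeneCatalog(GeneSet("causing", df$symbol[df$in_causing == 1], path),
                GeneSet("risk", df$symbol[df$in_risk == 1], path))
}

#' Load the bundled disease gene catalog
#'
#' Reads the packaged causing/risk gene lists (21 causing and 89 risk genes,
#' 3 shared, 107 total) shipped under \code{inst/extdata}.
#'
#' @return a \linkS4class{GeneCatalog}.
#' @examples
#' pdGeneCatalog()
#' @export
pdGeneCatalog <- function() {
    GeneCatalog(
        readGeneList(system.file("extdata", "pd_causing.txt",
                                 package = "padex"), "pd_causing"),
        readGeneList(system.file("extdata", "pd_risk.txt",
                                 package = "padex"), "pd_risk"))
}
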