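#' Classify genes by median age at onset
#'
#' Per gene, only those with strictly more than \code{minRecords} patient
#' records are classified (the others are flagged
#' \code{insufficient_data}). The median (even counts: mean of the central
#' pair) is binned as juvenile-onset (median <= 30 years), early-onset
#' (30 < median <= 50) or late-onset (> 50).
#'
#' @param records data.frame with columns \code{gene}, \code{aao_years}
#'   (one row per patient record; see \code{\link{readAAOTable}}).
#' @param minRecords record-count filter, strict (default 5: a gene needs
#'   > 5 records).
#' @return \linkS4class{DataFrame}, one row per gene: \code{gene},
#'   \code{n_records}, \code{median_aao}, \code{onset_class} in
#'   \{juvenile, early, late, insufficient_data\}.
#' @examples
#' df <- data.frame(gene = rep(c("A", "B"), c(6, 5)), aao_years = 20)
#' classifyOnset(df)   # A classified juvenile, B insufficient_data
#' @export
classifyOnset <- function(records, minRecords = 5L) {
    if (nrow(records) == 0L) stop("empty AAO record set")
    if (!all(c("gene", "aao_years") %in% colnames(records)))
        stop("records need columns 'gene' and 'aao_years'")
    if (any(!is.finite(records$aao_years)) || any(records$aao_years <= 0))
        stop("AAO values must be positive and finite")
    genes <- unique(records$gene)
    n <- vapply(genes, function(g) sum(records$gene == g), integer(1))
    med <- vapply(genes, function(g)
        stats::median(records$aao_years[records$gene == g]), numeric(1))
    cls <- ifelse(n <= minRecords, "insufficient_data",
           ifelse(med <= 30, "juvenile",
           ifelse(med <= 50, "early", "late")))
    med[cls == "insufficient_data"] <- NA_real_
    res <- S4Vectors::DataFrame(gene = genes, n_records = unname(n),
                                median_aao = unname(med),
                                onset_class = unname(cls))
    rownames(res) <- NULL
    S4Vectors::metadata(res) <- list(minRecords = minRecords)
    res
}

#' Associate onset classes with co-expression module membership
#'
#' Joins the per-gene onset classification to module labels by symbol and
#' reports, per module (plus the unassigned group): gene counts per onset
#' class, the median of the per-gene median AAOs, and the pooled-record
#' median. If at least two modules exist, the per-gene medians of the two
#' largest modules are additionally compared with a two-sided rank-sum test
#' (a descriptive extension; module-level medians remain the primary
#' summary).
#'
#' @param classes result of \code{\link{classifyOnset}}.
#' @param assignment a \linkS4class{ModuleAssignment}, or a named vector /
#'   two-column data.frame (\code{gene}, \code{module}) of labels
#'   (0 or "unassigned" = no module).
#' @param records optional original record table for pooled medians.
#' @return list: \code{counts} (module x onset-class table of classified
#'   genes), \code{median_of_gene_medians}, \code{pooled_median} (both
#'   named per module; NA where no data), \code{comparison} (list with
#'   \code{modules}, \code{U}, \code{p}, or NULL with
#'   \code{comparison_skipped = TRUE} when fewer than two modules exist).
#' @export
associateModules <- function(classes, assignment, records = NULL) {
    if (is(assignment, "ModuleAssignment")) {
        labels <- moduleLabels(assignment)
        mod <- ifelse(labels == 0L, "unassigned", paste0("M", labels))
        names(mod) <- names(labels)
    } else if (is.data.frame(assignment)) {
        mod <- as.character(assignment$module)
        mod[mod %in% c("0", "", "unassigned", NA)] <- "unassigned"
        names(mod) <- toupper(assignment$gene)
    } else {
        mod <- as.character(assignment)
        mod[mod %in% c("0", "", "unassigned") | is.na(mod)] <- "unassigned"
        names(mod) <- toupper(names(assignment))
    }
    keep <- classes[classes$onset_class != "insufficient_data", , drop = FALSE]
    geneMod <- mod[keep$gene]
    geneMod[is.na(geneMod)] <- "unassigned"
    modLevels <- c(sort(setdiff(unique(mod), "unassigned")), "unassigned")
    counts <- table(factor(geneMod, levels = modLevels),
                    factor(keep$onset_class,
                           levels = c("juvenile", "early", "late")))
    names(dimnames(counts)) <- c("module", "onset_class")
    medOfMed <- vapply(modLevels, function(m)
        if (any(geneMod == m)) stats::median(keep$median_aao[geneMod == m])
        else NA_real_, numeric(1))
    pooled <- rep(NA_real_, length(modLevels))
    names(pooled) <- modLevels
    if (!is.null(records)) {
        recMod <- mod[toupper(records$gene)]
        recMod[is.na(recMod)] <- "unassigned"
        keepRec <- records$gene %in% keep$gene
        for (m in modLevels)
            if (any(recMod == m & keepRec))
                pooled[m] <- stats::median(
                    records$aao_years[recMod == m & keepRec])
    }
    realMods <- setdiff(modLevels, "unassigned")
    comparison <- NULL
    skipped <- FALSE
    if (length(realMods) >= 2L) {
        sizes <- vapply(realMods, function(m) sum(geneMod == m), integer(1))
        top2 <- realMods[order(-sizes)][1:2]
        g1 <- keep$median_aao[geneMod == top2[1L]]
        g2 <- keep$median_aao[geneMod == top2[2L]]
        if (length(g1) && length(g2)) {
            ts <- rankSumTest(g1, g2)
            comparison <- list(modules = top2, U = ts$statistic,
                               p = ts$p.value)
        } else skipped <- TRUE
    } else skipped <- TRUE
    list(counts = counts,
         median_of_gene_medians = medOfMed,
         pooled_median = pooled,
         comparison = comparison,
         comparison_skipped = skipped)
}
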