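#' Default pipeline parameters
#'
#' The analysis defaults: top 50\% of tissues as preferential, RPKM >= 1 as
#' expressed, raw P < 0.01 for tissue enrichment, alpha = 0.05 for the
#' neuron rank-sum classification, soft-threshold power 7, static cut at
#' 0.85 with minimum module size 10, temporal-class margin 0.1 log2 units,
#' and the strict "> 5 records" AAO filter.
#'
#' @return named list of parameters.
#' @export
defaultPipelineParams <- function() {
    list(topFraction = 0.5, expressedThreshold = 1.0, tissueAlpha = 0.01,
         neuronAlpha = 0.05, power = 7, cutHeight = 0.85, minModuleSize = 10L,
         margin = 0.1, minRecords = 5L)
}

.loadStageExperiment <- function(stage, role, simFun, seed) {
    if (!is.null(stage$matrix)) {
        list(experiment = readExpressionTSV(stage$matrix, stage$annot),
             truth = NULL)
    } else if (!is.null(stage$simulate)) {
        args <- stage$simulate
        if (is.null(args$seed)) args$seed <- seed
        do.call(simFun, args)
    } else NULL
}

#' Run the full expression-pattern pipeline
#'
#' Executes catalog -> tissue preference -> neuron profile -> co-expression
#' modules -> onset association, writing per-stage TSV/JSON outputs and a
#' machine-readable run report. Stages whose inputs are absent from the
#' config are skipped and marked so in the report. All randomness (the
#' simulation-backed stages) derives from the global \code{seed}.
#'
#' @param config a list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{genes}{list(causing=, risk=) paths; default: the bundled
#'       catalog (\code{\link{pdGeneCatalog}}).}
#'     \item{tissue, neuron, development}{each either
#'       list(matrix=, annot=) TSV paths, or list(simulate=list(...)) of
#'       arguments to the matching simulator, or absent to skip. Simulated
#'       stages analyze their planted truth genes; file-backed stages
#'       analyze the catalog genes unless \code{genes = "all"} requests
#'       every gene of the matrix.}
#'     \item{aao}{list(records=path) or list(simulate=list(...)) (needs the
#'       development stage's truth or detected modules), or absent.}
#'     \item{params}{overrides of \code{\link{defaultPipelineParams}}.}
#'     \item{seed}{integer global seed (default 1).}
#'   }
#' @param outDir output directory (created if needed), or NULL to skip
#'   writing files.
#' @return the run report, an R list mirroring \code{report.json}.
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    params <- utils::modifyList(defaultPipelineParams(),
                                config$params %||% list())
    seed <- as.integer(config$seed %||% 1L)
    if (!is.null(outDir))
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    emit <- function(name, writer) {
        if (!is.null(outDir)) writer(file.path(outDir, name))
    }
    report <- list(software = paste0("padex ",
                       as.character(utils::packageVersion("padex"))),
                   seed = seed, timestamp = format(Sys.time(), tz = "UTC"),
                   params = params, stages = list())

    ## -- catalog ------------------------------------------------------
    catalog <- if (!is.null(config$genes)) {
        GeneCatalog(readGeneList(config$genes$causing, "causing"),
                    readGeneList(config$genes$risk, "risk"))
    } else pdGeneCatalog()
    report$catalog <- list(causing = length(causingGenes(catalog)),
                           risk = length(riskGenes(catalog)),
                           overlap = length(overlapGenes(catalog)),
                           union = length(pagGenes(catalog)),
                           overlap_genes = overlapGenes(catalog))
    report$stages$catalog <- "run"
    emit("catalog.tsv", function(p) writeCatalogTSV(catalog, p))

    ## -- tissue preference --------------------------------------------
    tiss <- .loadStageExperiment(config$tissue, "tissue",
                                 simulateTissueMatrix, seed + 1L)
    if (is.null(tiss)) {
        report$stages$tissue <- "skipped"
    } else {
        geneArg <- if (identical(config$tissue$genes, "all"))
                       rownames(tiss$experiment)
                   else if (!is.null(tiss$truth)) tiss$truth$signalGenes
                   else catalog
        enr <- enrichTissues(tiss$experiment, geneArg,
                             topFraction = params$topFraction,
                             expressedThreshold = params$expressedThreshold,
                             alpha = params$tissueAlpha)
        report$tissue <- list(
            n_tissues = nrow(enr),
            significant_tissues = enr$tissue[enr$significant],
            alpha = params$tissueAlpha)
        report$stages$tissue <- "run"
        emit("tissue_enrichment.tsv", function(p)
            utils::write.table(as.data.frame(enr), p, sep = "\t",
                               quote = FALSE, row.names = FALSE))
    }

    ## -- neuron profile -----------------------------------------------
    neur <- .loadStageExperiment(config$neuron, "neuron",
                                 simulateNeuronMatrix, seed + 2L)
    if (is.null(neur)) {
        report$stages$neuron <- "skipped"
    } else {
        geneArg <- if (identical(config$neuron$genes, "all"))
            rownames(neur$experiment)
        else if (!is.null(neur$truth))
            c(neur$truth$excShifted, neur$truth$inhShifted,
              neur$truth$background)
        else catalog
        prof <- profileNeuronTypes(neur$experiment, geneArg,
                                   alpha = params$neuronAlpha)
        report$neuron <- neuronSummary(prof)
        report$stages$neuron <- "run"
        emit("neuron_profile.tsv", function(p)
            utils::write.table(as.data.frame(prof), p, sep = "\t",
                               quote = FALSE, row.names = FALSE))
        emit("neuron_summary.json", function(p)
            jsonlite::write_json(report$neuron, p, auto_unbox = TRUE))
    }

    ## -- co-expression modules ----------------------------------------
    dev <- .loadStageExperiment(config$development, "development",
                                simulateDevelopmentMatrix, seed + 3L)
    assignment <- NULL
    if (is.null(dev)) {
        report$stages$modules <- "skipped"
    } else {
        norm <- normalizeFoldChange(dev$experiment)
        net <- buildNetwork(norm, power = params$power)
        assignment <- detectModules(net, cutHeight = params$cutHeight,
                                    minModuleSize = params$minModuleSize)
        if (length(moduleSizes(assignment)))
            assignment <- summarizeModules(assignment, norm, dev$experiment,
                                           margin = params$margin)
        report$modules <- list(
            n_modules = length(moduleSizes(assignment)),
            sizes = as.integer(moduleSizes(assignment)),
            temporal_class = temporalClass(assignment),
            n_unassigned = sum(moduleLabels(assignment) == 0L))
        report$stages$modules <- "run"
        labs <- moduleLabels(assignment)
        emit("modules.tsv", function(p)
            utils::write.table(
                data.frame(gene = names(labs),
                           module = ifelse(labs == 0L, "unassigned",
                                           paste0("M", labs))),
                p, sep = "\t", quote = FALSE, row.names = FALSE))
        emit("module_summary.json", function(p)
            jsonlite::write_json(report$modules, p, auto_unbox = TRUE))
    }

    ## -- onset association --------------------------------------------
    aaoCfg <- config$aao
    records <- NULL
    if (!is.null(aaoCfg$records)) {
        records <- readAAOTable(aaoCfg$records)
    } else if (!is.null(aaoCfg$simulate) && !is.null(dev$truth)) {
        args <- aaoCfg$simulate
        args$moduleTruth <- dev$truth
        if (is.null(args$seed)) args$seed <- seed + 4L
        records <- do.call(simulateAAO, args)
    }
    if (is.null(records)) {
        report$stages$onset <- "skipped"
    } else {
        classes <- classifyOnset(records, minRecords = params$minRecords)
        report$onset <- list(
            n_classified = sum(classes$onset_class != "insufficient_data"),
            n_insufficient = sum(classes$onset_class == "insufficient_data"),
            class_counts = as.list(table(
                classes$onset_class[classes$onset_class != "insufficient_data"])))
        if (!is.null(assignment)) {
            assoc <- associateModules(classes, assignment, records)
            report$onset$association <- list(
                counts = as.data.frame(assoc$counts),
                median_of_gene_medians = as.list(assoc$median_of_gene_medians),
                pooled_median = as.list(assoc$pooled_median),
                comparison = assoc$comparison,
                comparison_skipped = assoc$comparison_skipped)
            emit("onset_module_association.json", function(p)
                jsonlite::write_json(report$onset$association, p,
                                     auto_unbox = TRUE, digits = NA))
        }
        report$stages$onset <- "run"
        emit("onset_classes.tsv", function(p)
            utils::write.table(as.data.frame(classes), p, sep = "\t",
                               quote = FALSE, row.names = FALSE))
    }

    emit("report.json", function(p)
        jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                             null = "null"))
    report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
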