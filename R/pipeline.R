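## End-to-end orchestration: optional simulation, similarity, stability,
## association and network stages over a consistent bundle of tables, with
## pre-flight validation, a file manifest and a consolidated report.

#' Cross-table consistency checks
#'
#' Validates a loaded table bundle before any computation: every taxon in
#' the abundance tables must carry a partition label, every pair id must
#' resolve in its table, and genotype/phenotype samples must overlap the
#' abundance samples. Returns issues instead of erroring so callers can
#' report them all at once.
#'
#' @param mothers,offspring \linkS4class{AbundanceTable}s.
#' @param pairs a \linkS4class{PairMap}.
#' @param partition a \linkS4class{TaxonPartition}.
#' @param genotypes optional \linkS4class{GenotypeTable}.
#' @param functions optional \linkS4class{FunctionContentMatrix}.
#' @param phenotypes optional \linkS4class{PhenotypeTable}.
#' @return character vector of human-readable issues (empty when clean).
#' @export
validateInputs <- function(mothers, offspring, pairs, partition,
                           genotypes = NULL, functions = NULL,
                           phenotypes = NULL) {
    issues <- character(0)
    add <- function(fmt, ...) issues <<- c(issues, sprintf(fmt, ...))

    labelled <- names(partitionLabels(partition))
    for (what in c("mothers", "offspring")) {
        tab <- if (what == "mothers") mothers else offspring
        miss <- setdiff(taxonIDs(tab), labelled)
        for (m in miss)
            add("taxon '%s' in the %s table has no partition label", m, what)
    }
    pf <- pairFrame(pairs)
    for (m in setdiff(pf$mother, sampleIDs(mothers)))
        add("pair mother '%s' is absent from the mother table", m)
    for (o in setdiff(pf$offspring, sampleIDs(offspring)))
        add("pair offspring '%s' is absent from the offspring table", o)
    if (!is.null(genotypes)) {
        gs <- sampleIDs(genotypes)
        if (!length(intersect(gs, c(sampleIDs(mothers),
                                    sampleIDs(offspring)))))
            add("genotype samples do not overlap any abundance table")
    }
    if (!is.null(functions)) {
        covered <- taxonIDs(functions)
        tracked <- c(taxaByLabel(partition, "heritable"),
                     taxaByLabel(partition, "nonheritable"))
        miss <- setdiff(intersect(taxonIDs(mothers), tracked), covered)
        if (length(miss))
            add("%d analyzed taxa missing from the gene-content matrix (e.g. '%s')",
                length(miss), miss[1L])
    }
    if (!is.null(phenotypes)) {
        if (!length(intersect(sampleIDs(phenotypes), sampleIDs(mothers))))
            add("phenotype samples do not overlap the mother table")
    }
    issues
}

.pipelineDefaults <- function() {
    list(seed = 20160301,
         simulate = NULL, inputs = NULL, outDir = NULL,
         similarity = list(renormalize = TRUE),
         stability = list(reps = 25, label = c("heritable", "nonheritable")),
         associate = list(taxa = NULL),
         network = list(label = "heritable", rhoThreshold = 0.4,
                        pThreshold = 0.05, table = "mothers"),
         batchColumn = NULL)
}

.mergeConfig <- function(defaults, config) {
    for (nm in names(config)) {
        if (is.list(defaults[[nm]]) && is.list(config[[nm]]))
            defaults[[nm]] <- .mergeConfig(defaults[[nm]], config[[nm]])
        else defaults[[nm]] <- config[[nm]]
    }
    defaults
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> similarity -> stability -> associate ->
#' network over a directory of tables, writing every stage output as TSV
#' and returning a consolidated report. All randomness flows from
#' \code{config$seed}; a stage failure halts the run with a diagnostic
#' naming the stage.
#'
#' The config is a flat nested list (or the path of a YAML file with the
#' same structure): \code{outDir} (required), \code{seed},
#' \code{simulate} (list of \code{\link{synthParams}} overrides; set to an
#' empty list for defaults) or \code{inputs} (named file paths:
#' \code{mothers}, \code{offspring}, \code{pairs}, \code{partition}, and
#' optionally \code{genotypes}, \code{functions}, \code{phenotypes}),
#' plus per-stage settings (\code{similarity$renormalize},
#' \code{stability$reps}, \code{network$rhoThreshold}, ...). Batch-effect
#' adjustment is out of scope here (it belongs upstream with the batch
#' model that produced the merged tables); setting \code{batchColumn}
#' raises an explanatory error.
#'
#' @param config list or YAML file path.
#' @return A run report (class \code{rtRunReport}): per-stage status, the
#'   output-file manifest, warnings and headline summary statistics.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stopifnot(is.list(config))
    cfg <- .mergeConfig(.pipelineDefaults(), config)
    if (!is.null(cfg$batchColumn))
        stop(paste("batch-effect adjustment is not performed here: the",
                   "pipeline consumes tables that are already",
                   "batch-corrected upstream; drop 'batchColumn'"))
    if (is.null(cfg$outDir)) stop("config$outDir is required")
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)

    report <- list(stages = list(), manifest = character(0),
                   warnings = character(0), summaries = list(),
                   config = cfg)
    class(report) <- "rtRunReport"
    emit <- function(name, obj, writer) {
        path <- file.path(cfg$outDir, name)
        writer(obj, path)
        report$manifest <<- c(report$manifest, path)
        path
    }
    stage <- function(name, expr) {
        res <- tryCatch(expr, error = function(e)
            stop(sprintf("stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
        report$stages[[name]] <<- "ok"
        res
    }

    ## ---- load or simulate --------------------------------------------
    if (!is.null(cfg$simulate)) {
        bundle <- stage("simulate", {
            params <- do.call(synthParams, cfg$simulate)
            co <- simulateCohort(params, seed = cfg$seed)
            emit("mothers.tsv", cohortComponent(co, "mothers"),
                 writeAbundance)
            emit("offspring.tsv", cohortComponent(co, "offspring"),
                 writeAbundance)
            emit("pairs.tsv", cohortComponent(co, "pairs"), writePairs)
            emit("partition.tsv", cohortComponent(co, "partition"),
                 writePartition)
            emit("genotypes.tsv", cohortComponent(co, "genotypes"),
                 writeGenotypes)
            emit("functions.tsv", cohortComponent(co, "functions"),
                 writeFunctionMatrix)
            emit("phenotypes.tsv", cohortComponent(co, "phenotypes"),
                 writePhenotypes)
            list(mothers = cohortComponent(co, "mothers"),
                 offspring = cohortComponent(co, "offspring"),
                 pairs = cohortComponent(co, "pairs"),
                 partition = cohortComponent(co, "partition"),
                 genotypes = cohortComponent(co, "genotypes"),
                 functions = cohortComponent(co, "functions"),
                 phenotypes = cohortComponent(co, "phenotypes"),
                 params = cohortComponent(co, "params"))
        })
    } else {
        bundle <- stage("load", {
            ip <- cfg$inputs
            need <- c("mothers", "offspring", "pairs", "partition")
            miss <- setdiff(need, names(ip))
            if (length(miss))
                stop(sprintf("missing input path(s): %s",
                             paste(miss, collapse = ", ")))
            gone <- unlist(ip)[!file.exists(unlist(ip))]
            if (length(gone))
                stop(sprintf("input file(s) not found: %s",
                             paste(gone, collapse = ", ")))
            list(mothers = readAbundance(ip$mothers),
                 offspring = readAbundance(ip$offspring),
                 pairs = readPairs(ip$pairs),
                 partition = readPartition(ip$partition),
                 genotypes = if (!is.null(ip$genotypes))
                     readGenotypes(ip$genotypes) else NULL,
                 functions = if (!is.null(ip$functions))
                     readFunctionMatrix(ip$functions) else NULL,
                 phenotypes = if (!is.null(ip$phenotypes))
                     readPhenotypes(ip$phenotypes) else NULL,
                 params = NULL)
        })
    }

    issues <- stage("validate", validateInputs(
        bundle$mothers, bundle$offspring, bundle$pairs, bundle$partition,
        bundle$genotypes, bundle$functions, bundle$phenotypes))
    if (length(issues))
        stop(sprintf("pre-flight validation failed:\n  - %s",
                     paste(issues, collapse = "\n  - ")), call. = FALSE)

    ## ---- similarity ---------------------------------------------------
    stage("similarity", {
        simH <- pairwiseSimilarity(bundle$mothers, bundle$offspring,
                                   bundle$pairs, bundle$partition,
                                   "heritable",
                                   renormalize = cfg$similarity$renormalize)
        simN <- pairwiseSimilarity(bundle$mothers, bundle$offspring,
                                   bundle$pairs, bundle$partition,
                                   "nonheritable",
                                   renormalize = cfg$similarity$renormalize)
        emit("similarity_records.tsv", rbind(simH, simN), .writeTSV)
        cmp <- comparePartitions(simH, simN)
        emit("similarity_summary.tsv",
             cbind(cmp$summary,
                   p_value = cmp$test$p.value,
                   statistic = cmp$test$statistic), .writeTSV)
        for (lab in c("heritable", "nonheritable")) {
            emit(sprintf("flow_%s.tsv", lab),
                 flowTable(bundle$mothers, bundle$offspring,
                           bundle$partition, lab), .writeTSV)
            for (gen in c("mothers", "offspring")) {
                gtot <- generationTotals(bundle[[gen]], bundle$partition,
                                         lab)
                report$summaries[[sprintf("%s_%s_total", gen, lab)]] <-
                    c(mean = gtot$mean, se = gtot$se)
            }
        }
        report$summaries$similarity <- cmp$summary
        NULL
    })

    ## ---- stability ------------------------------------------------------
    if (!is.null(bundle$functions)) stage("stability", {
        fits <- list()
        for (lab in cfg$stability$label) {
            for (gen in c("mothers", "offspring")) {
                f <- cohortStability(bundle[[gen]], bundle$functions,
                                     bundle$partition, lab,
                                     reps = cfg$stability$reps,
                                     seed = cfg$seed + 11)
                f$generation <- gen; f$label <- lab
                fits[[paste(gen, lab)]] <- f
            }
        }
        allFits <- do.call(rbind, fits)
        emit("stability_fits.tsv", allFits, .writeTSV)
        if (all(c("heritable", "nonheritable") %in% cfg$stability$label)) {
            cmp <- compareStability(fits[["mothers heritable"]],
                                    fits[["mothers nonheritable"]])
            emit("stability_comparison.tsv", cmp, .writeTSV)
            report$summaries$stability <- cmp
        }
        NULL
    }) else report$stages$stability <- "skipped (no gene-content matrix)"

    ## ---- association ----------------------------------------------------
    hasAssoc <- !is.null(bundle$genotypes) &&
        (!is.null(bundle$phenotypes) || !is.null(cfg$associate$taxa))
    if (hasAssoc) stage("associate", {
        recs <- list()
        taxa <- cfg$associate$taxa
        if (is.null(taxa))
            taxa <- intersect(.keyTaxa, taxonIDs(bundle$mothers))
        if (length(taxa))
            recs$taxa <- associateTraits(bundle$genotypes, bundle$mothers,
                                         traitList = taxa)
        if (!is.null(bundle$phenotypes))
            recs$vfa <- associateTraits(bundle$genotypes,
                                        bundle$phenotypes)
        out <- do.call(rbind, recs)
        emit("associations.tsv", out, .writeTSV)
        report$summaries$significantAssociations <-
            sum(out$tier == "significant")
        NULL
    }) else report$stages$associate <- "skipped (no genotypes)"

    ## ---- network --------------------------------------------------------
    stage("network", {
        edges <- buildNetwork(bundle[[cfg$network$table]],
                              bundle$partition,
                              label = cfg$network$label,
                              rhoThreshold = cfg$network$rhoThreshold,
                              pThreshold = cfg$network$pThreshold)
        emit("network_edges.tsv", edges, writeEdgeList)
        emit("network_degrees.tsv", degreeSummary(edges), .writeTSV)
        report$summaries$edgeCount <- nrow(edges)
        NULL
    })

    report
}

#' @export
print.rtRunReport <- function(x, ...) {
    cat("rumenTransmit pipeline report\n")
    for (nm in names(x$stages))
        cat(sprintf("  %-11s %s\n", nm, x$stages[[nm]]))
    cat(sprintf("  outputs: %d files in %s\n", length(x$manifest),
                x$config$outDir))
    if (!is.null(x$summaries$similarity)) {
        s <- x$summaries$similarity
        cat(sprintf("  similarity: %s\n",
                    paste(sprintf("%s %.3f +/- %.3f", s$label, s$mean,
                                  s$se), collapse = ", ")))
    }
    if (!is.null(x$summaries$edgeCount))
        cat(sprintf("  network edges: %d\n", x$summaries$edgeCount))
    invisible(x)
}
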