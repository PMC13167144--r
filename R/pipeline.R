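#' Pipeline configuration
#'
#' Declarative configuration for the modular pipeline.  Every step reads and
#' writes only plain CSV/JSON/.Q/text artifacts under `outputDir`, so any
#' stage can be run standalone or substituted by a custom tool producing
#' compatible files.
#'
#' Defaults (all overridable here or by CLI flags, flags winning):
#' \describe{
#'   \item{inputDir}{directory of run files (required).}
#'   \item{format}{"auto" | "admixture" | "structure" | "faststructure".}
#'   \item{labelsFile}{optional population label file.}
#'   \item{cdMethod}{"louvain" (default) or "mcl".}
#'   \item{cdSeed}{community-detection seed, default 42.}
#'   \item{forceSingleTol}{optional; force one mode when every pairwise
#'     dissimilarity is below it (off by default).}
#'   \item{minEdgeSimilarity}{Louvain edge floor, default 0.7.}
#'   \item{mclInflation}{MCL inflation, default 2.}
#'   \item{anchorCriterion}{"best" (default) or "major".}
#'   \item{reorderReference}{"largest_k" (default) or "smallest_k".}
#'   \item{emptyClusterEpsilon}{default 0.01.}
#'   \item{plots}{logical, render figures in the plot step (default TRUE).}
#'   \item{plotFormat}{"pdf" (default) or "png".}
#'   \item{models}{named list model ID -> input dir (compModels step only).}
#'   \item{referenceModel}{reference model ID (default: first of models).}
#'   \item{outputDir}{artifact directory (required).}
#' }
#'
#' @param inputDir,outputDir required paths.
#' @param ... overrides of the defaults listed above.
#' @param configFile optional YAML file of settings, overridden by `...`.
#' @return A list of class "PipelineConfig".
#' @export
pipelineConfig <- function(inputDir = NULL, outputDir = NULL, ...,
                           configFile = NULL) {
    defaults <- list(inputDir = NULL, format = "auto", labelsFile = NULL,
                     cdMethod = "louvain", cdSeed = 42L,
                     forceSingleTol = NULL, minEdgeSimilarity = 0.7,
                     mclInflation = 2.0, anchorCriterion = "best",
                     reorderReference = "largest_k",
                     emptyClusterEpsilon = 0.01, plots = TRUE,
                     plotFormat = "pdf", models = NULL,
                     referenceModel = NULL, outputDir = NULL)
    cfg <- defaults
    if (!is.null(configFile)) {
        if (!file.exists(configFile))
            stop(sprintf("config file '%s' does not exist", configFile))
        cfg <- utils::modifyList(cfg, yaml::read_yaml(configFile))
    }
    over <- list(...)
    if (!is.null(inputDir)) over$inputDir <- inputDir
    if (!is.null(outputDir)) over$outputDir <- outputDir
    cfg <- utils::modifyList(cfg, over)
    stopifnot(cfg$cdMethod %in% c("louvain", "mcl"),
              cfg$anchorCriterion %in% c("best", "major"),
              cfg$reorderReference %in% c("largest_k", "smallest_k"),
              cfg$plotFormat %in% c("pdf", "png"),
              is.null(cfg$forceSingleTol) || cfg$forceSingleTol >= 0,
              cfg$emptyClusterEpsilon >= 0, cfg$minEdgeSimilarity >= 0)
    structure(cfg, class = "PipelineConfig")
}

logLine <- function(cfg, fmt, ...) {
    dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
    msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   sprintf(fmt, ...))
    cat(msg, "\n", sep = "", file = file.path(cfg$outputDir, "pipeline.log"),
        append = TRUE)
    invisible(msg)
}

configHash <- function(cfg) {
    f <- tempfile()
    on.exit(unlink(f))
    dput(cfg[order(names(unclass(cfg)))], file = f)
    unname(tools::md5sum(f))
}

pairwiseCsvPath <- function(cfg, k)
    file.path(cfg$outputDir, "align", sprintf("pairwise_K%d.csv", k))
modesCsvPath <- function(cfg) file.path(cfg$outputDir, "modes",
                                        "modes_summary.csv")

loadInput <- function(cfg) {
    loadRunCollection(cfg$inputDir, format = cfg$format,
                      labels = cfg$labelsFile)
}

# ---- step implementations --------------------------------------------------

stepAlign <- function(cfg) {
    coll <- loadInput(cfg)
    dir.create(file.path(cfg$outputDir, "align"), recursive = TRUE,
               showWarnings = FALSE)
    byK <- runsByK(coll)
    for (kc in names(byK)) {
        runsK <- byK[[kc]]
        ids <- vapply(runsK, runID, character(1))
        rows <- list()
        r <- length(runsK)
        if (r == 1L) {
            al <- alignSameK(runsK[[1L]], runsK[[1L]])
            rows[[1L]] <- data.frame(
                run_a = ids[1L], run_b = ids[1L], K_a = as.integer(kc),
                K_b = as.integer(kc), cost = fmtNum(al@cost),
                similarity = fmtNum(al@similarity),
                assignment = paste(al@assignment, collapse = ","),
                stringsAsFactors = FALSE)
        } else {
            for (i in seq_len(r - 1L)) for (j in seq((i + 1L), r)) {
                al <- alignSameK(runsK[[i]], runsK[[j]])
                rows[[length(rows) + 1L]] <- data.frame(
                    run_a = ids[i], run_b = ids[j], K_a = as.integer(kc),
                    K_b = as.integer(kc), cost = fmtNum(al@cost),
                    similarity = fmtNum(al@similarity),
                    assignment = paste(al@assignment, collapse = ","),
                    stringsAsFactors = FALSE)
            }
        }
        utils::write.csv(do.call(rbind, rows),
                         pairwiseCsvPath(cfg, as.integer(kc)),
                         row.names = FALSE)
    }
    logLine(cfg, "align: %d K levels, %d runs", length(byK),
            length(runs(coll)))
    invisible(cfg)
}

# rebuild a SimilarityNetwork and pairwise matchings from a pairwise CSV
networkFromCsv <- function(csv, runsK) {
    ids <- vapply(runsK, runID, character(1))
    tab <- utils::read.csv(csv, stringsAsFactors = FALSE,
                           colClasses = c(assignment = "character"))
    r <- length(ids)
    w <- diag(1, r)
    asg <- list()
    for (i in seq_len(nrow(tab))) {
        a <- match(tab$run_a[i], ids); b <- match(tab$run_b[i], ids)
        if (is.na(a) || is.na(b)) next
        w[a, b] <- w[b, a] <- as.numeric(tab$similarity[i])
        asg[[paste(tab$run_a[i], tab$run_b[i], sep = "|")]] <-
            as.integer(strsplit(tab$assignment[i], ",")[[1L]])
    }
    k <- nClusters(runsK[[1L]])
    list(net = new("SimilarityNetwork", weights = w, runIDs = ids,
                   k = as.integer(k)),
         assignments = asg)
}

stepModes <- function(cfg) {
    coll <- loadInput(cfg)
    byK <- runsByK(coll)
    for (kc in names(byK))
        stopIfMissingArtifact(pairwiseCsvPath(cfg, as.integer(kc)), "align")
    dir.create(file.path(cfg$outputDir, "modes"), recursive = TRUE,
               showWarnings = FALSE)
    rowsOut <- list()
    for (kc in names(byK)) {
        runsK <- byK[[kc]]
        cache <- networkFromCsv(pairwiseCsvPath(cfg, as.integer(kc)), runsK)
        # reuse matchings already on disk instead of re-solving
        alignTo <- function(target, source) {
            key <- paste(runID(target), runID(source), sep = "|")
            rkey <- paste(runID(source), runID(target), sep = "|")
            a <- cache$assignments[[key]]
            if (!is.null(a))
                return(alignmentResult(a, length(a), length(a), 0))
            a <- cache$assignments[[rkey]]
            if (!is.null(a))  # stored as target->source; invert
                return(alignmentResult(order(a), length(a), length(a), 0))
            alignSameK(target, source)
        }
        modes <- summarizeModes(runsK, net = cache$net, method = cfg$cdMethod,
                                forceSingleTol = cfg$forceSingleTol,
                                seed = cfg$cdSeed,
                                minEdgeSimilarity = cfg$minEdgeSimilarity,
                                mclInflation = cfg$mclInflation,
                                alignTo = alignTo)
        for (m in modes) {
            writeQFile(memberships(representative(m)),
                       file.path(cfg$outputDir, "modes",
                                 paste0(modeID(m), ".Q")))
            rowsOut[[length(rowsOut) + 1L]] <- data.frame(
                mode_id = modeID(m), K = modeK(m), size = modeSize(m),
                within_similarity = fmtNum(withinSimilarity(m)),
                members = paste(modeMembers(m), collapse = ";"),
                stringsAsFactors = FALSE)
        }
    }
    utils::write.csv(do.call(rbind, rowsOut), modesCsvPath(cfg),
                     row.names = FALSE, quote = FALSE)
    logLine(cfg, "modes: %d modes", length(rowsOut))
    invisible(cfg)
}

# read the modes step's artifacts back into Mode objects (sizes/similarities
# from the CSV, representatives from the .Q files)
readModesArtifacts <- function(cfg) {
    stopIfMissingArtifact(modesCsvPath(cfg), "modes")
    tab <- utils::read.csv(modesCsvPath(cfg), stringsAsFactors = FALSE)
    modesByK <- list()
    for (i in seq_len(nrow(tab))) {
        id <- tab$mode_id[i]
        qf <- file.path(cfg$outputDir, "modes", paste0(id, ".Q"))
        stopIfMissingArtifact(qf, "modes")
        m <- new("Mode", modeID = id, k = as.integer(tab$K[i]),
                 memberRuns = strsplit(tab$members[i], ";")[[1L]],
                 representative = readAdmixtureQ(qf, runID = id),
                 withinSimilarity = as.numeric(tab$within_similarity[i]))
        kc <- as.character(tab$K[i])
        modesByK[[kc]] <- c(modesByK[[kc]], stats::setNames(list(m), id))
    }
    modesByK[order(as.integer(names(modesByK)))]
}

stepAcrossK <- function(cfg) {
    modesByK <- readModesArtifacts(cfg)
    g <- alignAcrossK(modesByK, criterion = cfg$anchorCriterion)
    dir.create(file.path(cfg$outputDir, "acrossk"), recursive = TRUE,
               showWarnings = FALSE)
    writeLines(alignmentPatternLines(g),
               file.path(cfg$outputDir, "acrossk", "alignment_pattern.txt"))
    gj <- list(
        k_values = g@kValues,
        modes = lapply(g@modes, function(m) list(
            mode_id = modeID(m), K = modeK(m), size = modeSize(m),
            within_similarity = withinSimilarity(m),
            global_labels = g@clusterLabels[[modeID(m)]])),
        anchors = lapply(g@anchorPairs, function(p) list(
            lower = p$lower, upper = p$upper,
            cost = p$alignment@cost, similarity = p$alignment@similarity,
            assignment = p$alignment@assignment)),
        edges = lapply(g@edges, function(e) list(
            lower = e$lower, upper = e$upper, is_anchor = e$isAnchor,
            cost = e$alignment@cost, similarity = e$alignment@similarity,
            assignment = e$alignment@assignment)))
    jsonlite::write_json(gj, file.path(cfg$outputDir, "acrossk", "graph.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    logLine(cfg, "acrossk: %d cross-K edges, %d anchors", length(g@edges),
            length(g@anchorPairs))
    invisible(g)
}

readGraphArtifacts <- function(cfg) {
    modesByK <- readModesArtifacts(cfg)
    gp <- file.path(cfg$outputDir, "acrossk", "graph.json")
    stopIfMissingArtifact(gp, "acrossk")
    gj <- jsonlite::read_json(gp, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
    allModes <- list()
    for (lv in modesByK) for (m in lv) allModes[[modeID(m)]] <- m
    mkAl <- function(x, kLow, kHigh) alignmentResult(
        as.integer(x$assignment), kHigh, kLow, as.numeric(x$cost))
    anchors <- lapply(gj$anchors, function(p) {
        kLow <- modeK(allModes[[p$lower]]); kHigh <- modeK(allModes[[p$upper]])
        list(lower = p$lower, upper = p$upper,
             alignment = mkAl(p, kLow, kHigh))
    })
    edges <- lapply(gj$edges, function(e) {
        kLow <- modeK(allModes[[e$lower]]); kHigh <- modeK(allModes[[e$upper]])
        list(lower = e$lower, upper = e$upper,
             alignment = mkAl(e, kLow, kHigh), isAnchor = isTRUE(e$is_anchor))
    })
    labels <- lapply(gj$modes, function(m) as.integer(m$global_labels))
    names(labels) <- vapply(gj$modes, `[[`, character(1), "mode_id")
    new("ModeAlignmentGraph", modes = allModes,
        kValues = as.integer(gj$k_values), anchorPairs = anchors,
        edges = edges, clusterLabels = labels)
}

stepPlot <- function(cfg) {
    if (!isTRUE(cfg$plots)) return(invisible(NULL))
    coll <- loadInput(cfg)
    g <- readGraphArtifacts(cfg)
    dir.create(file.path(cfg$outputDir, "plots"), recursive = TRUE,
               showWarnings = FALSE)
    ext <- cfg$plotFormat
    kv <- g@kValues
    refK <- if (cfg$reorderReference == "largest_k") max(kv) else min(kv)
    refID <- sprintf("K%dM1", refK)
    ord <- reorderIndividuals(representative(g@modes[[refID]]),
                              popLabels(coll), referenceMode = refID)
    for (m in g@modes)
        plotModeBarplot(representative(m), order = ord,
                        clusterLabels = g@clusterLabels[[modeID(m)]],
                        labels = popLabels(coll),
                        path = file.path(cfg$outputDir, "plots",
                                         sprintf("mode_%s.%s", modeID(m), ext)))
    plotMultipartite(g, order = ord, labels = popLabels(coll),
                     path = file.path(cfg$outputDir, "plots",
                                      paste0("multipartite.", ext)))
    plotAlignmentPattern(g, path = file.path(cfg$outputDir, "plots",
                                             paste0("alignment_pattern.",
                                                    ext)))
    logLine(cfg, "plot: figures written (%s)", ext)
    invisible(NULL)
}

stepCompModels <- function(cfg) {
    if (is.null(cfg$models) || length(cfg$models) < 2L)
        stop("compModels requires cfg$models: a named list of >= 2 input dirs")
    colls <- lapply(cfg$models, function(d)
        loadRunCollection(d, format = cfg$format, labels = cfg$labelsFile))
    ref <- cfg$referenceModel %||% names(cfg$models)[1L]
    cmp <- compareModels(colls, reference = ref,
                         epsilon = cfg$emptyClusterEpsilon,
                         method = cfg$cdMethod,
                         forceSingleTol = cfg$forceSingleTol,
                         seed = cfg$cdSeed,
                         minEdgeSimilarity = cfg$minEdgeSimilarity,
                         mclInflation = cfg$mclInflation,
                         criterion = cfg$anchorCriterion)
    dir.create(file.path(cfg$outputDir, "compmodels"), recursive = TRUE,
               showWarnings = FALSE)
    tab <- cmp@table
    tab$within_similarity <- fmtNum(tab$within_similarity)
    tab$similarity_to_reference <- ifelse(
        is.na(tab$similarity_to_reference), "",
        fmtNum(tab$similarity_to_reference))
    utils::write.csv(tab, file.path(cfg$outputDir, "compmodels",
                                    "comparison_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    if (isTRUE(cfg$plots)) {
        labels <- popLabels(colls[[1L]])
        kmax <- max(cmp@table$k[cmp@table$model == ref])
        refMajor <- cmp@models[[ref]]$modesByK[[as.character(kmax)]][[1L]]
        ord <- reorderIndividuals(representative(refMajor), labels,
                                  referenceMode = modeID(refMajor))
        plotModelComparison(cmp, order = ord, labels = labels,
                            path = file.path(cfg$outputDir, "compmodels",
                                             paste0("comparison.",
                                                    cfg$plotFormat)))
    }
    logLine(cfg, "compModels: %d models, reference %s", length(colls), ref)
    invisible(cmp)
}

#' Run one pipeline step or the integrated pipeline
#'
#' Steps: `align` (pairwise same-K alignments -> align/pairwise_K*.csv),
#' `modes` (mode detection -> modes/modes_summary.csv + mode .Q files),
#' `acrossk` (anchored cross-K alignment -> acrossk/alignment_pattern.txt +
#' graph.json), `plot` (figures), `compModels` (model comparison), and
#' `pipeline` (align, modes, acrossk, plot in sequence).  A standalone step
#' only requires the upstream artifacts listed above to exist in
#' `cfg$outputDir`; a missing artifact raises an error naming the file and
#' the step that produces it.  With a fixed config and seed the data
#' artifacts are byte-reproducible, and stepwise execution writes the same
#' bytes as the integrated pipeline.
#'
#' @param step one of "align", "modes", "acrossk", "plot", "compModels",
#'   "pipeline".
#' @param cfg a [pipelineConfig()].
#' @return The step's main in-memory result, invisibly (NULL for plot).
#' @export
runStep <- function(step = c("pipeline", "align", "modes", "acrossk", "plot",
                             "compModels"), cfg) {
    step <- match.arg(step)
    stopifnot(inherits(cfg, "PipelineConfig"))
    if (step != "compModels" && is.null(cfg$inputDir))
        stop("cfg$inputDir is required")
    if (is.null(cfg$outputDir)) stop("cfg$outputDir is required")
    t0 <- proc.time()[["elapsed"]]
    logLine(cfg, "step %s: start (config %s, seed %d)", step, configHash(cfg),
            cfg$cdSeed)
    out <- switch(step,
        align = stepAlign(cfg),
        modes = stepModes(cfg),
        acrossk = stepAcrossK(cfg),
        plot = stepPlot(cfg),
        compModels = stepCompModels(cfg),
        pipeline = {
            stepAlign(cfg)
            stepModes(cfg)
            g <- stepAcrossK(cfg)
            stepPlot(cfg)
            g
        })
    logLine(cfg, "step %s: done in %.2fs", step,
            proc.time()[["elapsed"]] - t0)
    invisible(out)
}

#' @rdname runStep
#' @export
runPipeline <- function(cfg) runStep("pipeline", cfg)
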