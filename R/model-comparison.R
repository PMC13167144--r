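#' Flag clusters with negligible membership
#'
#' Some programs (notably fastStructure at large K) produce clusters with
#' negligible total membership.  A cluster is flagged when its mean
#' membership over individuals is below `epsilon`.
#'
#' @param m a [MembershipMatrix-class].
#' @param epsilon mean-membership threshold (default 0.01).
#' @return Integer vector of flagged cluster indices (possibly empty).
#' @export
flagEmptyClusters <- function(m, epsilon = 0.01) {
    stopifnot(epsilon >= 0)
    which(colMeans(memberships(m)) < epsilon)
}

#' Compare modes across models
#'
#' Runs the full per-model pipeline (similarity networks, mode detection,
#' cross-K anchored alignment) independently for each model, then aligns
#' each non-reference model's modes to the reference model's major mode at
#' every K present in both (same-K alignment on representatives) so cluster
#' colors are comparable across models.  Per-model results are identical to
#' running the single-model pipeline on that model's runs alone; cross-model
#' alignment only relabels, it never alters representative values.
#'
#' @param collections named list: model ID -> [RunCollection-class].  All
#'   collections must share N.
#' @param reference reference model ID (default: first name).
#' @param epsilon empty-cluster threshold passed to [flagEmptyClusters()].
#' @param criterion anchor criterion for the per-model cross-K alignment.
#' @inheritParams detectModes
#' @return A [ModelComparison-class].
#' @export
compareModels <- function(collections, reference = names(collections)[1L],
                          epsilon = 0.01, method = "louvain",
                          forceSingleTol = NULL, seed = 42L,
                          minEdgeSimilarity = 0.7, mclInflation = 2.0,
                          criterion = "best") {
    if (length(collections) < 2L)
        stop("model comparison needs at least 2 models")
    if (is.null(names(collections)) || any(!nzchar(names(collections))))
        stop("collections must be a named list (model IDs)")
    if (!reference %in% names(collections))
        stop(sprintf("reference model '%s' not among models", reference))
    ns <- vapply(collections, nIndividuals, integer(1))
    if (length(unique(ns)) != 1L)
        stop("models disagree on the number of individuals: ",
             paste(sprintf("%s: N=%d", names(ns), ns), collapse = ", "))

    models <- lapply(collections, function(coll) {
        byK <- detectModesByK(coll, method = method,
                              forceSingleTol = forceSingleTol, seed = seed,
                              minEdgeSimilarity = minEdgeSimilarity,
                              mclInflation = mclInflation)
        modesByK <- lapply(byK, `[[`, "modes")
        list(modesByK = modesByK, graph = alignAcrossK(modesByK, criterion))
    })

    refModes <- models[[reference]]$modesByK
    refLabels <- models[[reference]]$graph@clusterLabels
    labels <- list()
    rows <- list()
    for (mid in names(models)) {
        mod <- models[[mid]]
        labs <- list()
        for (kc in names(mod$modesByK)) {
            refHasK <- kc %in% names(refModes)
            refMajor <- if (refHasK) refModes[[kc]][[1L]] else NULL
            for (mode in mod$modesByK[[kc]]) {
                id <- modeID(mode)
                simToRef <- NA_real_
                if (mid == reference || !refHasK) {
                    labs[[id]] <- mod$graph@clusterLabels[[id]]
                    if (mid == reference && refHasK)
                        simToRef <- if (identical(id, modeID(refMajor))) 1 else
                            alignSameK(representative(refMajor),
                                       representative(mode))@similarity
                } else {
                    al <- alignSameK(representative(refMajor),
                                     representative(mode))
                    labs[[id]] <- refLabels[[modeID(refMajor)]][al@assignment]
                    simToRef <- al@similarity
                }
                flagged <- flagEmptyClusters(representative(mode), epsilon)
                rows[[length(rows) + 1L]] <- data.frame(
                    model = mid, k = modeK(mode), mode = id,
                    size = modeSize(mode),
                    within_similarity = withinSimilarity(mode),
                    similarity_to_reference = simToRef,
                    empty_clusters = paste(labs[[id]][flagged],
                                           collapse = ";"),
                    stringsAsFactors = FALSE)
            }
        }
        labels[[mid]] <- labs
    }
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$k, match(tab$model, names(models)), tab$mode), ]
    rownames(tab) <- NULL
    new("ModelComparison", models = models, reference = reference,
        table = tab, labels = labels)
}

#' Interleaved-by-K model comparison figure
#'
#' K increases top to bottom; at each K there is one row band per model (in
#' model order), with alternating background shading distinguishing the
#' models.  Bars are colored by the cross-model-aligned global labels, and
#' clusters flagged as near-empty are marked with an asterisk above the bar.
#'
#' @param cmp a [ModelComparison-class].
#' @param order optional [DisplayOrder-class].
#' @param labels optional [PopulationLabels-class].
#' @param path output file (.pdf or .png).
#' @param width,height,dpi device geometry.
#' @return `path`, invisibly.
#' @export
plotModelComparison <- function(cmp, order = NULL, labels = NULL, path,
                                width = 10, height = NULL, dpi = 150) {
    tab <- cmp@table
    bands <- unique(tab[, c("k", "model")])
    nb <- nrow(bands)
    if (is.null(height)) height <- max(3, 1.3 * nb)
    maxLab <- max(unlist(lapply(cmp@labels, unlist)))
    pal <- clusterPalette(maxLab)
    openDevice(path, width, height, dpi)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(0.5, 4, 0.5, 1))
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1))
    bandH <- 1 / nb
    for (b in seq_len(nb)) {
        k <- bands$k[b]; mid <- bands$model[b]
        y1 <- 1 - (b - 1) * bandH; y0 <- y1 - bandH
        shade <- match(mid, names(cmp@models)) %% 2L == 1L
        if (shade)
            graphics::rect(-0.08, y0, 1.02, y1, col = "gray92", border = NA,
                           xpd = NA)
        sub <- tab[tab$k == k & tab$model == mid, , drop = FALSE]
        nm <- nrow(sub)
        cellW <- 1 / nm
        for (j in seq_len(nm)) {
            id <- sub$mode[j]
            mode <- findMode(cmp, mid, id)
            q <- memberships(representative(mode))
            ord <- if (is.null(order)) seq_len(nrow(q)) else order@order
            gl <- cmp@labels[[mid]][[id]]
            x0 <- (j - 1) * cellW + 0.04 * cellW
            x1 <- j * cellW - 0.04 * cellW
            by0 <- y0 + 0.22 * bandH; by1 <- y1 - 0.16 * bandH
            drawBars(q, ord, pal[gl], x0, x1, by0, by1)
            graphics::text(x0, by1 + 0.004,
                           sprintf("%s:%s (%d)", mid, id, modeSize(mode)),
                           cex = 0.5, adj = c(0, 0))
            flagged <- flagEmptyClusters(representative(mode))
            if (length(flagged))
                graphics::text(x1, by1 + 0.004,
                               paste0("* empty: ",
                                      paste(gl[flagged], collapse = ",")),
                               cex = 0.5, adj = c(1, 0), col = "red3")
        }
        graphics::mtext(sprintf("K=%d %s", k, mid), side = 2,
                        at = mean(c(y0, y1)), cex = 0.55, las = 1, line = 0.3)
    }
    invisible(path)
}

findMode <- function(cmp, modelID, modeID) {
    for (lv in cmp@models[[modelID]]$modesByK)
        if (modeID %in% names(lv)) return(lv[[modeID]])
    stop(sprintf("mode '%s' not found for model '%s'", modeID, modelID))
}
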