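#' @name accessors
#' @title Accessors for Qmodes classes
#' @description Slot accessors: `memberships()` returns the numeric N x K
#'   matrix, `nIndividuals()`/`nClusters()` its dimensions, `runID()` and
#'   `modelID()` the run metadata; `runs()`, `runsByK()` and `popLabels()`
#'   access a [RunCollection-class]; `runIDs()` and `similarityWeights()` a
#'   [SimilarityNetwork-class]; `modeID()`, `modeK()`, `modeSize()`,
#'   `modeMembers()`, `representative()` and `withinSimilarity()` a
#'   [Mode-class].
#' @param x object.
#' @return The corresponding slot value (see Description).
NULL

#' @rdname accessors
#' @export
setGeneric("memberships", function(x) standardGeneric("memberships"))
#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))
#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))
#' @rdname accessors
#' @export
setGeneric("runID", function(x) standardGeneric("runID"))
#' @rdname accessors
#' @export
setGeneric("modelID", function(x) standardGeneric("modelID"))
#' @rdname accessors
#' @export
setGeneric("runs", function(x) standardGeneric("runs"))
#' @rdname accessors
#' @export
setGeneric("runsByK", function(x) standardGeneric("runsByK"))
#' @rdname accessors
#' @export
setGeneric("popLabels", function(x) standardGeneric("popLabels"))
#' @rdname accessors
#' @export
setGeneric("runIDs", function(x) standardGeneric("runIDs"))
#' @rdname accessors
#' @export
setGeneric("similarityWeights", function(x) standardGeneric("similarityWeights"))
#' @rdname accessors
#' @export
setGeneric("modeID", function(x) standardGeneric("modeID"))
#' @rdname accessors
#' @export
setGeneric("modeK", function(x) standardGeneric("modeK"))
#' @rdname accessors
#' @export
setGeneric("modeSize", function(x) standardGeneric("modeSize"))
#' @rdname accessors
#' @export
setGeneric("modeMembers", function(x) standardGeneric("modeMembers"))
#' @rdname accessors
#' @export
setGeneric("representative", function(x) standardGeneric("representative"))
#' @rdname accessors
#' @export
setGeneric("withinSimilarity", function(x) standardGeneric("withinSimilarity"))

setMethod("memberships", "MembershipMatrix", function(x) x@values)
setMethod("nIndividuals", "MembershipMatrix", function(x) nrow(x@values))
setMethod("nClusters", "MembershipMatrix", function(x) ncol(x@values))
setMethod("runID", "MembershipMatrix", function(x) x@runID)
setMethod("modelID", "MembershipMatrix", function(x) x@modelID)

setMethod("runs", "RunCollection", function(x) x@runs)
setMethod("nIndividuals", "RunCollection", function(x) nrow(x@runs[[1L]]@values))
setMethod("popLabels", "RunCollection", function(x) x@labels)
setMethod("runsByK", "RunCollection", function(x) {
    ks <- vapply(x@runs, function(r) ncol(r@values), integer(1))
    out <- split(x@runs, ks)
    out[order(as.integer(names(out)))]
})

setMethod("runIDs", "SimilarityNetwork", function(x) x@runIDs)
setMethod("similarityWeights", "SimilarityNetwork", function(x) x@weights)

setMethod("modeID", "Mode", function(x) x@modeID)
setMethod("modeK", "Mode", function(x) x@k)
setMethod("modeSize", "Mode", function(x) length(x@memberRuns))
setMethod("modeMembers", "Mode", function(x) x@memberRuns)
setMethod("representative", "Mode", function(x) x@representative)
setMethod("withinSimilarity", "Mode", function(x) x@withinSimilarity)

setMethod("show", "MembershipMatrix", function(object) {
    cat(sprintf("MembershipMatrix '%s': N = %d individuals, K = %d clusters\n",
                object@runID, nrow(object@values), ncol(object@values)))
    if (!is.na(object@modelID)) cat("  model:", object@modelID, "\n")
})

setMethod("show", "RunCollection", function(object) {
    ks <- vapply(object@runs, function(r) ncol(r@values), integer(1))
    tab <- table(ks)
    cat(sprintf("RunCollection: %d runs, N = %d individuals\n",
                length(object@runs), nrow(object@runs[[1L]]@values)))
    cat("  runs per K:",
        paste(sprintf("K=%s: %d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
    if (!is.null(object@labels))
        cat("  population labels:",
            length(object@labels@groupOrder), "groups\n")
})

setMethod("show", "AlignmentResult", function(object) {
    cat(sprintf("AlignmentResult: K%d -> K%d, cost = %.6g, similarity = %.6g\n",
                object@sourceK, object@targetK, object@cost, object@similarity))
    cat("  assignment:", paste(object@assignment, collapse = " "), "\n")
})

setMethod("show", "SimilarityNetwork", function(object) {
    w <- object@weights[upper.tri(object@weights)]
    cat(sprintf("SimilarityNetwork: %d runs at K = %d\n",
                length(object@runIDs), object@k))
    if (length(w))
        cat(sprintf("  pairwise similarity: min %.4f, mean %.4f, max %.4f\n",
                    min(w), mean(w), max(w)))
})

setMethod("show", "Mode", function(object) {
    cat(sprintf("Mode %s: K = %d, size = %d, within-mode similarity = %.4f\n",
                object@modeID, object@k, length(object@memberRuns),
                object@withinSimilarity))
})

setMethod("show", "ModeAlignmentGraph", function(object) {
    cat(sprintf("ModeAlignmentGraph: %d modes over K in {%s}\n",
                length(object@modes),
                paste(object@kValues, collapse = ", ")))
    for (ap in names(object@anchorPairs)) {
        p <- object@anchorPairs[[ap]]
        cat(sprintf("  anchor %s: %s - %s (cost %.4g)\n", ap, p$lower, p$upper,
                    p$alignment@cost))
    }
})

setMethod("show", "ModelComparison", function(object) {
    cat(sprintf("ModelComparison: %d models (reference '%s')\n",
                length(object@models), object@reference))
    print(head(object@table, 10L))
})
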