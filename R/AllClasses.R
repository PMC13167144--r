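#' MembershipMatrix: one run's N x K row-stochastic membership matrix
#'
#' Container for a single clustering run's membership coefficients.  Entry
#' (i, c) is individual i's estimated membership in latent cluster c; rows sum
#' to 1.  Use [membershipMatrix()] to construct (it validates and repairs
#' small row-sum drift); slot access goes through the accessors
#' [memberships()], [nIndividuals()], [nClusters()], [runID()] and
#' [modelID()].
#'
#' @slot values numeric matrix, N x K, entries in \[0, 1\], rows summing to 1.
#' @slot runID character scalar identifying the run (typically the filename).
#' @slot modelID optional character tag for the program/setting that produced
#'   the run (used by [compareModels()]).
#' @aliases MembershipMatrix
#' @exportClass MembershipMatrix
setClass("MembershipMatrix",
    representation(values = "matrix", runID = "character",
                   modelID = "character"),
    prototype(runID = "run", modelID = NA_character_))

setValidity("MembershipMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be numeric")
    if (nrow(v) < 1L || ncol(v) < 1L) return("need N >= 1 and K >= 1")
    if (anyNA(v)) return("values contain NA")
    if (any(v < -1e-9) || any(v > 1 + 1e-9))
        return("membership coefficients must lie in [0, 1]")
    rs <- rowSums(v)
    if (any(abs(rs - 1) > 1e-6))
        return(sprintf("row sums deviate from 1 beyond 1e-6 (max drift %.3g)",
                       max(abs(rs - 1))))
    if (length(object@runID) != 1L) return("runID must be a single string")
    TRUE
})

#' Construct a MembershipMatrix
#'
#' Validates and row-normalizes a numeric matrix of membership coefficients.
#' Rows whose sum drifts from 1 by at most 0.05 (rounding drift typical of
#' ADMIXTURE/fastStructure output files) are silently renormalized; larger
#' drift is an error, since repairing it would hide corrupt input.
#'
#' @param values numeric N x K matrix.
#' @param runID run identifier (default "run").
#' @param modelID optional model tag.
#' @param normalize renormalize rows to sum 1 (default TRUE).
#' @return A [MembershipMatrix-class] object.
#' @examples
#' q <- membershipMatrix(rbind(c(0.6, 0.4), c(0.1, 0.9)))
#' nClusters(q)
#' @export
membershipMatrix <- function(values, runID = "run", modelID = NA_character_,
                             normalize = TRUE) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (anyNA(values)) stop("membership matrix contains non-numeric entries")
    if (any(values < 0)) stop("membership coefficients must be nonnegative")
    if (normalize) {
        rs <- rowSums(values)
        drift <- abs(rs - 1)
        if (any(drift > 0.05)) {
            bad <- which(drift > 0.05)[1L]
            stop(sprintf(
                "row %d of '%s' sums to %.4f; drift beyond 0.05 is not repairable",
                bad, runID, rs[bad]))
        }
        values <- values / rs
    }
    dimnames(values) <- NULL
    new("MembershipMatrix", values = values, runID = as.character(runID),
        modelID = as.character(modelID))
}

#' RunCollection: replicate runs grouped by K
#'
#' Holds all R runs of a study.  All runs must share the same number of
#' individuals N; K may differ between runs (and usually does).  Access runs
#' with [runs()], grouped by K with [runsByK()]; optional population labels
#' with [popLabels()].
#'
#' @slot runs list of [MembershipMatrix-class] objects.
#' @slot labels a [PopulationLabels-class] object or NULL.
#' @aliases RunCollection
#' @exportClass RunCollection
setClass("RunCollection",
    representation(runs = "list", labels = "ANY"),
    prototype(labels = NULL))

setValidity("RunCollection", function(object) {
    if (length(object@runs) < 1L) return("collection must contain >= 1 run")
    if (!all(vapply(object@runs, is, logical(1), "MembershipMatrix")))
        return("all elements of runs must be MembershipMatrix objects")
    ns <- vapply(object@runs, function(r) nrow(r@values), integer(1))
    if (length(unique(ns)) != 1L) {
        ids <- vapply(object@runs, function(r) r@runID, character(1))
        off <- ids[ns != ns[1L]]
        return(paste0("runs disagree on N: ", paste(off, collapse = ", ")))
    }
    if (!is.null(object@labels)) {
        if (!is(object@labels, "PopulationLabels"))
            return("labels must be PopulationLabels or NULL")
        if (length(object@labels@labels) != ns[1L])
            return("label count differs from N")
    }
    TRUE
})

#' Construct a RunCollection
#' @param runs list of [MembershipMatrix-class] objects sharing N.
#' @param labels optional [PopulationLabels-class].
#' @return A [RunCollection-class] object.
#' @export
runCollection <- function(runs, labels = NULL) {
    new("RunCollection", runs = runs, labels = labels)
}

#' PopulationLabels: one label per individual
#'
#' @slot labels character vector, one label per individual, in row order.
#' @slot groupOrder distinct labels in display order (each exactly once).
#' @aliases PopulationLabels
#' @exportClass PopulationLabels
setClass("PopulationLabels",
    representation(labels = "character", groupOrder = "character"))

setValidity("PopulationLabels", function(object) {
    if (length(object@labels) < 1L) return("need >= 1 label")
    u <- unique(object@labels)
    if (!setequal(u, object@groupOrder) ||
        anyDuplicated(object@groupOrder))
        return("groupOrder must list each distinct label exactly once")
    TRUE
})

#' Construct PopulationLabels
#' @param labels character vector of per-individual labels.
#' @param groupOrder display order of the distinct labels (default: order of
#'   first appearance).
#' @return A [PopulationLabels-class] object.
#' @export
populationLabels <- function(labels, groupOrder = unique(labels)) {
    new("PopulationLabels", labels = as.character(labels),
        groupOrder = as.character(groupOrder))
}

#' AlignmentResult: an optimal cluster matching plus its cost and similarity
#'
#' The matching maps every source cluster (of the larger-or-equal-K run) to
#' exactly one target cluster (of the smaller-or-equal-K run); every target
#' cluster has at least one preimage, so equal K forces a bijection.  Cost is
#' \eqn{\|Q_a - M(Q_b)\|_F^2 / (2N)} where \eqn{M} sums the source columns
#' mapped to each target cluster; similarity is 1 - cost.
#'
#' @slot sourceK K of the source (larger-or-equal-K) run.
#' @slot targetK K of the target run.
#' @slot assignment integer vector of length sourceK; entry c is the 1-based
#'   target cluster of source cluster c.
#' @slot cost alignment cost in \[0, 1\].
#' @slot similarity 1 - cost.
#' @aliases AlignmentResult
#' @exportClass AlignmentResult
setClass("AlignmentResult",
    representation(sourceK = "integer", targetK = "integer",
                   assignment = "integer", cost = "numeric",
                   similarity = "numeric"))

setValidity("AlignmentResult", function(object) {
    a <- object@assignment
    if (length(a) != object@sourceK) return("assignment must cover all source clusters")
    if (any(a < 1L) || any(a > object@targetK)) return("assignment out of range")
    if (length(unique(a)) != object@targetK)
        return("assignment must be surjective onto target clusters")
    if (abs(object@similarity - (1 - object@cost)) > 1e-9)
        return("similarity must equal 1 - cost")
    if (object@cost < -1e-9 || object@cost > 1 + 1e-9)
        return("cost must lie in [0, 1]")
    TRUE
})

alignmentResult <- function(assignment, sourceK, targetK, cost) {
    new("AlignmentResult", sourceK = as.integer(sourceK),
        targetK = as.integer(targetK), assignment = as.integer(assignment),
        cost = as.numeric(cost), similarity = 1 - as.numeric(cost))
}

#' SimilarityNetwork: pairwise optimal alignment similarities at one K
#'
#' @slot weights symmetric R x R matrix of optimal pairwise similarities,
#'   diagonal 1, entries in \[0, 1\].
#' @slot runIDs character vector of R run identifiers.
#' @slot k the shared number of clusters.
#' @aliases SimilarityNetwork
#' @exportClass SimilarityNetwork
setClass("SimilarityNetwork",
    representation(weights = "matrix", runIDs = "character", k = "integer"))

setValidity("SimilarityNetwork", function(object) {
    w <- object@weights
    r <- length(object@runIDs)
    if (nrow(w) != r || ncol(w) != r) return("weights must be R x R")
    if (max(abs(w - t(w))) > 1e-9) return("weights must be symmetric")
    if (any(abs(diag(w) - 1) > 1e-9)) return("diagonal must equal 1")
    if (any(w < -1e-9) || any(w > 1 + 1e-9)) return("weights must lie in [0, 1]")
    TRUE
})

#' Mode: a set of mutually aligned runs with a consensus representative
#'
#' @slot modeID string such as "K5M1" (mode 1 at K = 5; M1 is the largest).
#' @slot k number of clusters.
#' @slot memberRuns run IDs of the member runs.
#' @slot representative consensus [MembershipMatrix-class] (member mean after
#'   alignment to the mode medoid, rows renormalized).
#' @slot withinSimilarity mean pairwise similarity among members (1 for
#'   singletons).
#' @aliases Mode
#' @exportClass Mode
setClass("Mode",
    representation(modeID = "character", k = "integer",
                   memberRuns = "character",
                   representative = "MembershipMatrix",
                   withinSimilarity = "numeric"))

setValidity("Mode", function(object) {
    if (length(object@memberRuns) < 1L) return("mode must have >= 1 member")
    if (ncol(object@representative@values) != object@k)
        return("representative K mismatch")
    ws <- object@withinSimilarity
    if (ws < -1e-9 || ws > 1 + 1e-9) return("withinSimilarity must lie in [0, 1]")
    TRUE
})

#' ModeAlignmentGraph: modes by K with anchored cross-K matchings
#'
#' Backbone of the multipartite bar-plot graph and the alignment pattern
#' graph: all modes keyed by ID, the anchor mode pair chosen for every
#' adjacent pair of present K values, the cross-K [AlignmentResult-class] for
#' every mode pair between adjacent K values, and a consistent global cluster
#' labeling (color slots 1..K_max) for every mode.
#'
#' @slot modes named list of [Mode-class] objects keyed by mode ID.
#' @slot kValues sorted integer vector of present K values.
#' @slot anchorPairs named list (one per adjacent K pair "K1-K2") with
#'   elements `lower`, `upper` (mode IDs) and `alignment`.
#' @slot edges named list keyed "modeLow|modeHigh" with elements `lower`,
#'   `upper`, `alignment`, `isAnchor`.
#' @slot clusterLabels named list: mode ID -> integer vector mapping local
#'   cluster index to global label.
#' @aliases ModeAlignmentGraph
#' @exportClass ModeAlignmentGraph
setClass("ModeAlignmentGraph",
    representation(modes = "list", kValues = "integer", anchorPairs = "list",
                   edges = "list", clusterLabels = "list"))

#' DisplayOrder: a display permutation of individuals
#'
#' @slot order integer permutation of 1..N (display position -> individual).
#' @slot referenceMode mode ID whose representative defined the order.
#' @aliases DisplayOrder
#' @exportClass DisplayOrder
setClass("DisplayOrder",
    representation(order = "integer", referenceMode = "character"))

setValidity("DisplayOrder", function(object) {
    n <- length(object@order)
    if (!identical(sort(object@order), seq_len(n)))
        return("order must be a permutation of 1..N")
    TRUE
})

#' ModelComparison: per-model modes interleaved by K
#'
#' Result of [compareModels()]: independent per-model pipelines plus
#' cross-model alignments of each model's modes to the reference model's
#' major mode at each shared K.
#'
#' @slot models named list: model ID -> list(modes, graph).
#' @slot reference reference model ID.
#' @slot table data.frame summary (model, k, mode, size, within similarity,
#'   similarity to reference, empty-cluster flags).
#' @slot labels named list: model ID -> named list of per-mode global label
#'   vectors comparable across models.
#' @aliases ModelComparison
#' @exportClass ModelComparison
setClass("ModelComparison",
    representation(models = "list", reference = "character",
                   table = "data.frame", labels = "list"))
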