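#' Build the pairwise alignment-similarity network for same-K runs
#'
#' Computes the optimal alignment similarity for all R(R-1)/2 unordered run
#' pairs (each computed once and mirrored) and returns the weighted network
#' used for mode detection.
#'
#' @param runsK list of [MembershipMatrix-class] objects sharing K and N.
#' @return A [SimilarityNetwork-class].
#' @export
buildSimilarityNetwork <- function(runsK) {
    if (!length(runsK)) stop("need >= 1 run")
    ks <- vapply(runsK, nClusters, integer(1))
    if (length(unique(ks)) != 1L)
        stop("all runs in a similarity network must share K")
    r <- length(runsK)
    ids <- vapply(runsK, runID, character(1))
    w <- diag(1, r)
    if (r > 1L) {
        for (i in seq_len(r - 1L)) {
            for (j in seq((i + 1L), r)) {
                s <- alignSameK(runsK[[i]], runsK[[j]])@similarity
                w[i, j] <- s
                w[j, i] <- s
            }
        }
    }
    new("SimilarityNetwork", weights = w, runIDs = ids, k = ks[1L])
}

#' Partition a similarity network into modes by community detection
#'
#' Returns a partition of the runs (a list of run-ID vectors), ordered by the
#' mode-numbering rules: decreasing size, ties broken by higher within-mode
#' similarity, then by smallest member run ID.
#'
#' Both methods operate on the similarity network after edges below an
#' absolute similarity floor (`minEdgeSimilarity`) are removed.  The floor is
#' load-bearing: Newman-Girvan modularity (Louvain) is invariant to uniform
#' weight rescaling, so on a raw network of uniformly *dissimilar* runs it
#' would return one community instead of R singletons, and Markov clustering
#' mixes flow across a dense graph whose off-block weights are substantial.
#' `"louvain"` runs Louvain modularity optimization; `"mcl"` runs Markov
#' clustering with the given inflation.
#'
#' If `forceSingleTol` is set and every pairwise dissimilarity (1 -
#' similarity) is below it, a single mode containing all runs is returned and
#' community detection is bypassed — useful when minor disagreements are
#' acceptable for summarization.
#'
#' @param net a [SimilarityNetwork-class].
#' @param method "louvain" or "mcl".
#' @param forceSingleTol optional tolerance (e.g. 1e-6); see Details.
#' @param seed RNG seed for the community detection (default 42).
#' @param minEdgeSimilarity absolute similarity floor for Louvain edges
#'   (default 0.7; 0 keeps every edge).
#' @param mclInflation inflation exponent for MCL (default 2).
#' @return List of character vectors of run IDs (one per mode, M1 first).
#' @export
detectModes <- function(net, method = c("louvain", "mcl"),
                        forceSingleTol = NULL, seed = 42L,
                        minEdgeSimilarity = 0.7, mclInflation = 2.0) {
    method <- match.arg(method)
    w <- net@weights
    ids <- net@runIDs
    r <- length(ids)
    if (!is.null(forceSingleTol)) {
        diss <- 1 - w[upper.tri(w)]
        if (r == 1L || all(diss < forceSingleTol))
            return(list(ids))
    }
    if (r == 1L) return(list(ids))
    a <- w
    a[a < minEdgeSimilarity] <- 0   # absolute similarity floor (see Details)
    membership <- if (method == "louvain") {
        diag(a) <- 0
        g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                                 weighted = TRUE)
        if (igraph::ecount(g) == 0L) {
            seq_len(r)
        } else {
            cl <- withSeed(seed, igraph::cluster_louvain(
                g, weights = igraph::E(g)$weight))
            igraph::membership(cl)
        }
    } else {
        diag(a) <- 1   # self-loops keep isolated runs as attractors
        mclPartition(a, inflation = mclInflation)
    }
    parts <- split(ids, membership)
    orderModes(unname(parts), net)
}

# Markov clustering: expansion/inflation on the column-stochastic similarity
# matrix; clusters are connected components of the converged matrix.
mclPartition <- function(w, inflation = 2.0, maxIter = 200L, tol = 1e-9,
                         prune = 1e-8) {
    normalizeCols <- function(m) sweep(m, 2L, pmax(colSums(m), .Machine$double.eps), "/")
    M <- normalizeCols(w)
    for (it in seq_len(maxIter)) {
        M2 <- normalizeCols((M %*% M)^inflation)
        M2[M2 < prune] <- 0
        M2 <- normalizeCols(M2)
        if (max(abs(M2 - M)) < tol) { M <- M2; break }
        M <- M2
    }
    adj <- (M > 0) | (t(M) > 0)
    g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected",
                                             weighted = NULL, diag = FALSE)
    igraph::components(g)$membership
}

# order partitions by decreasing size, then decreasing within-mode
# similarity, then smallest member run ID
orderModes <- function(parts, net) {
    sizes <- lengths(parts)
    sims <- vapply(parts, withinModeSimilarity, numeric(1), net = net)
    minid <- vapply(parts, function(p) min(p), character(1))
    o <- order(-sizes, -sims, minid)
    lapply(parts[o], function(p) sort(p))
}

#' Mean pairwise alignment similarity among a mode's members
#'
#' The mean of the network weights over all unordered member pairs; defined
#' as 1 for singleton modes.
#'
#' @param members character vector of run IDs (subset of the network's runs).
#' @param net a [SimilarityNetwork-class].
#' @return Numeric in \[0, 1\].
#' @export
withinModeSimilarity <- function(members, net) {
    idx <- match(members, net@runIDs)
    if (anyNA(idx)) stop("unknown run ID in members")
    if (length(idx) < 2L) return(1)
    sub <- net@weights[idx, idx]
    mean(sub[upper.tri(sub)])
}

#' Consensus representative of aligned mode members
#'
#' Entrywise mean of member matrices that have already been aligned to a
#' common cluster labeling, with rows renormalized.  Equals the single member
#' for singleton modes.
#'
#' @param members list of aligned [MembershipMatrix-class] objects.
#' @param runID run ID to give the consensus matrix.
#' @return A [MembershipMatrix-class].
#' @export
modeRepresentative <- function(members, runID = "consensus") {
    if (!length(members)) stop("cannot form a representative of zero members")
    acc <- Reduce(`+`, lapply(members, memberships)) / length(members)
    membershipMatrix(acc, runID = runID)
}

#' Detect and summarize modes for the runs at one K
#'
#' Runs [detectModes()], then for each detected mode aligns all members to
#' the mode medoid (the member with the highest total similarity to the other
#' members; ties broken by run ID) and computes the consensus representative
#' and within-mode similarity.  Modes are numbered K<k>M1, K<k>M2, ... by
#' decreasing size.
#'
#' @param runsK list of same-K [MembershipMatrix-class] objects.
#' @param net optional precomputed [SimilarityNetwork-class] for these runs.
#' @param alignTo optional function(target, source) returning an
#'   [AlignmentResult-class]; defaults to [alignSameK()].  Exposed so the
#'   standalone pipeline step can reuse matchings already on disk.
#' @inheritParams detectModes
#' @return Named list of [Mode-class] objects in mode-number order.
#' @export
summarizeModes <- function(runsK, net = NULL, method = "louvain",
                           forceSingleTol = NULL, seed = 42L,
                           minEdgeSimilarity = 0.7, mclInflation = 2.0,
                           alignTo = NULL) {
    if (is.null(net)) net <- buildSimilarityNetwork(runsK)
    parts <- detectModes(net, method = method, forceSingleTol = forceSingleTol,
                         seed = seed, minEdgeSimilarity = minEdgeSimilarity,
                         mclInflation = mclInflation)
    k <- net@k
    ids <- vapply(runsK, runID, character(1))
    if (is.null(alignTo)) alignTo <- function(target, source) alignSameK(target, source)
    out <- list()
    for (m in seq_along(parts)) {
        mem <- parts[[m]]
        idx <- match(mem, ids)
        medoid <- mem[modeMedoid(mem, net)]
        target <- runsK[[match(medoid, ids)]]
        aligned <- lapply(idx, function(i) {
            r <- runsK[[i]]
            if (identical(runID(r), medoid)) return(r)
            al <- alignTo(target, r)
            applyMatching(r, al@assignment, targetK = k)
        })
        id <- sprintf("K%dM%d", k, m)
        consensus <- modeRepresentative(aligned, runID = id)
        out[[id]] <- new("Mode", modeID = id, k = as.integer(k),
                         memberRuns = mem, representative = consensus,
                         withinSimilarity = withinModeSimilarity(mem, net))
    }
    out
}

# index (within members) of the member with highest total similarity to the
# other members; ties broken by run ID order
modeMedoid <- function(members, net) {
    idx <- match(members, net@runIDs)
    if (length(idx) == 1L) return(1L)
    sub <- net@weights[idx, idx]
    tot <- rowSums(sub) - diag(sub)
    o <- order(-tot, members)
    o[1L]
}

#' Detect modes for every K in a collection
#'
#' Convenience wrapper: builds the similarity network and summarizes modes
#' for each K present in the collection.
#'
#' @param collection a [RunCollection-class].
#' @inheritParams detectModes
#' @return Named list (by K value) of lists: `network` and `modes`.
#' @export
detectModesByK <- function(collection, method = "louvain",
                           forceSingleTol = NULL, seed = 42L,
                           minEdgeSimilarity = 0.7, mclInflation = 2.0) {
    byK <- runsByK(collection)
    out <- lapply(byK, function(runsK) {
        net <- buildSimilarityNetwork(runsK)
        modes <- summarizeModes(runsK, net = net, method = method,
                                forceSingleTol = forceSingleTol, seed = seed,
                                minEdgeSimilarity = minEdgeSimilarity,
                                mclInflation = mclInflation)
        list(network = net, modes = modes)
    })
    names(out) <- names(byK)
    out
}
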