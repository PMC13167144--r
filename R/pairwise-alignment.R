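#' Alignment cost of a given cluster matching
#'
#' The cost functional used throughout the package.  For a target run
#' \eqn{Q_a} (N x K1), a source run \eqn{Q_b} (N x K2, K2 >= K1) and a
#' surjective matching m from source clusters onto target clusters,
#' \deqn{cost = \|Q_a - M(Q_b)\|_F^2 / (2N),}
#' where \eqn{M(Q_b)} has column d equal to the SUM of the source columns
#' mapped to d.  Summing (rather than averaging) conserves membership mass,
#' so a clean column split aligns across K with cost exactly 0.  Because both
#' \eqn{Q_a} and \eqn{M(Q_b)} are row-stochastic, the cost lies in \[0, 1\];
#' similarity = 1 - cost.
#'
#' @param qa target [MembershipMatrix-class] (smaller-or-equal K).
#' @param qb source [MembershipMatrix-class].
#' @param assignment integer vector of length K(qb); entry c is the 1-based
#'   target cluster that source cluster c maps to.  Must be surjective.
#' @return Cost in \[0, 1\].
#' @examples
#' qa <- membershipMatrix(rbind(c(0.6, 0.4), c(0.1, 0.9)))
#' qb <- membershipMatrix(rbind(c(0.5, 0.5), c(0.3, 0.7)))
#' alignmentCost(qa, qb, c(1, 2))  # 0.025
#' @export
alignmentCost <- function(qa, qb, assignment) {
    A <- memberships(qa); B <- memberships(qb)
    if (nrow(A) != nrow(B)) stop("runs have different numbers of individuals")
    k1 <- ncol(A); k2 <- ncol(B)
    assignment <- as.integer(assignment)
    if (length(assignment) != k2)
        stop("assignment must map every source cluster")
    if (any(assignment < 1L) || any(assignment > k1) ||
        length(unique(assignment)) != k1)
        stop("assignment must be surjective onto the target clusters")
    merged <- vapply(seq_len(k1),
                     function(d) rowSums(B[, assignment == d, drop = FALSE]),
                     numeric(nrow(B)))
    if (nrow(A) == 1L) merged <- matrix(merged, nrow = 1L)
    sum((A - merged)^2) / (2 * nrow(A))
}

# merged/permuted source matrix under a matching (used by mode consensus and
# by the cross-K composition); returns a MembershipMatrix with targetK columns
#' Apply a cluster matching to a membership matrix
#'
#' Returns the source matrix with columns permuted (equal K) or summed into
#' their matched target clusters (cross K), i.e. the matrix the alignment
#' cost compares against the target.
#'
#' @param m source [MembershipMatrix-class].
#' @param assignment surjective map, as in [alignmentCost()].
#' @param targetK number of target clusters.
#' @return A [MembershipMatrix-class] with `targetK` columns.
#' @export
applyMatching <- function(m, assignment, targetK = max(assignment)) {
    B <- memberships(m)
    assignment <- as.integer(assignment)
    out <- vapply(seq_len(targetK),
                  function(d) rowSums(B[, assignment == d, drop = FALSE]),
                  numeric(nrow(B)))
    if (nrow(B) == 1L) out <- matrix(out, nrow = 1L)
    membershipMatrix(out, runID = runID(m), modelID = modelID(m),
                     normalize = FALSE)
}

# squared-distance cost matrix between source columns (rows) and target
# columns (cols)
columnCostMatrix <- function(A, B) {
    k1 <- ncol(A); k2 <- ncol(B)
    C <- matrix(0, k2, k1)
    for (c in seq_len(k2))
        for (d in seq_len(k1))
            C[c, d] <- sum((B[, c] - A[, d])^2)
    C
}

#' Optimal one-to-one alignment of two same-K runs
#'
#' Solves the one-to-one cluster matching minimizing [alignmentCost()].  The
#' objective decomposes over matched column pairs, so the optimum is found by
#' linear sum assignment on the K x K matrix of squared column distances
#' (identical optimum to the binary-program formulation).  Among cost-tied
#' optimal bijections the lexicographically smallest assignment vector is
#' returned, so results are deterministic.
#'
#' @param qa target [MembershipMatrix-class].
#' @param qb source [MembershipMatrix-class] with the same K and N.
#' @return An [AlignmentResult-class]; `assignment[c]` is the target cluster
#'   matched to source cluster c.
#' @examples
#' qa <- membershipMatrix(rbind(c(0.8, 0.2), c(0.3, 0.7)))
#' qb <- membershipMatrix(memberships(qa)[, c(2, 1)])  # swapped columns
#' alignSameK(qa, qb)  # recovers the swap, cost 0
#' @export
alignSameK <- function(qa, qb) {
    A <- memberships(qa); B <- memberships(qb)
    if (ncol(A) != ncol(B))
        stop("K differs between runs; use alignCrossK for unequal K")
    if (nrow(A) != nrow(B)) stop("runs have different numbers of individuals")
    k <- ncol(A)
    if (k == 1L) return(alignmentResult(1L, 1L, 1L, 0))
    C <- columnCostMatrix(A, B)
    sol <- cpp_lsap_lex(C, 1e-9)
    assignment <- sol$assignment + 1L
    cost <- max(0, sol$cost / (2 * nrow(A)))
    alignmentResult(assignment, k, k, cost)
}

#' Optimal surjective cross-K alignment
#'
#' Aligns a larger-K run onto a smaller-K run: every source (large-K) cluster
#' maps to exactly one target cluster and every target cluster receives at
#' least one source cluster — the feasible set of the binary program with
#' variables \eqn{x_{cd} \in \{0,1\}}, \eqn{\sum_d x_{cd} = 1} and
#' \eqn{\sum_c x_{cd} \ge 1}.  Solved exactly: each surjection is a set
#' partition of the source clusters into K_small non-empty blocks plus a
#' bijection of blocks onto targets, so the solver enumerates the partitions
#' (with Gram-matrix incremental costs) and solves a linear assignment per
#' partition.  The partition count is capped (default 5e5, reached only for
#' large K at a large K gap); adjacent K values remain cheap at any K.
#'
#' @param qSmall target [MembershipMatrix-class] (smaller K).
#' @param qLarge source [MembershipMatrix-class] (larger K).
#' @param maxPartitions guard on the number of enumerated set partitions.
#' @return An [AlignmentResult-class] mapping large-K clusters onto small-K
#'   clusters.
#' @export
alignCrossK <- function(qSmall, qLarge, maxPartitions = 5e5) {
    A <- memberships(qSmall); B <- memberships(qLarge)
    k1 <- ncol(A); k2 <- ncol(B)
    if (k1 >= k2)
        stop("alignCrossK requires K(qSmall) < K(qLarge); ",
             "use alignSameK for equal K or swap the arguments")
    if (nrow(A) != nrow(B)) stop("runs have different numbers of individuals")
    np <- stirling2(k2, k1)
    if (np > maxPartitions)
        stop(sprintf(paste0("exact surjective alignment would enumerate %g set ",
                            "partitions (cap %g); K = %d onto K = %d is too ",
                            "large a gap"), np, maxPartitions, k2, k1))
    qaa <- colSums(A^2)
    Bm <- crossprod(B, A)          # k2 x k1 inner products
    G <- crossprod(B)              # k2 x k2 Gram
    sol <- cpp_surjection_align(qaa, Bm, G, 1e-9)
    assignment <- sol$assignment + 1L
    cost <- max(0, sol$cost / (2 * nrow(A)))
    alignmentResult(assignment, k2, k1, cost)
}

# Stirling number of the second kind (count of partitions of n into m blocks)
stirling2 <- function(n, m) {
    S <- matrix(0, n + 1L, m + 1L)
    S[1L, 1L] <- 1
    for (i in seq_len(n))
        for (j in seq_len(min(i, m)))
            S[i + 1L, j + 1L] <- S[i, j] + j * S[i, j + 1L]
    S[n + 1L, m + 1L]
}

#' Brute-force alignment oracle
#'
#' Exhaustively enumerates all K! bijections (equal K) or all surjective maps
#' (unequal K) and returns the exact optimum, breaking cost ties by the
#' lexicographically smallest assignment vector.  Intended as an independent
#' test oracle; refuses K above 7.
#'
#' @param qa first run; the one with smaller (or equal) K becomes the target.
#' @param qb second run.
#' @return An [AlignmentResult-class].
#' @export
bruteForceAlign <- function(qa, qb) {
    if (nClusters(qa) > nClusters(qb)) { tmp <- qa; qa <- qb; qb <- tmp }
    k1 <- nClusters(qa); k2 <- nClusters(qb)
    if (k2 > 7L) stop("bruteForceAlign refuses K > 7 (combinatorial blow-up)")
    cands <- if (k1 == k2) {
        lapply(allPermutations(k2), identity)
    } else {
        allSurjections(k2, k1)
    }
    best <- NULL; bestCost <- Inf
    for (a in cands) {
        cost <- alignmentCost(qa, qb, a)
        if (cost < bestCost - 1e-12 ||
            (cost <= bestCost + 1e-12 && !is.null(best) && lexLess(a, best))) {
            best <- a; bestCost <- min(bestCost, cost)
        } else if (is.null(best)) {
            best <- a; bestCost <- cost
        }
    }
    alignmentResult(best, k2, k1, bestCost)
}

lexLess <- function(a, b) {
    d <- which(a != b)
    length(d) > 0L && a[d[1L]] < b[d[1L]]
}

allPermutations <- function(n) {
    if (n == 1L) return(list(1L))
    out <- list()
    for (p in allPermutations(n - 1L))
        for (pos in seq_len(n))
            out[[length(out) + 1L]] <- as.integer(append(p, n, after = pos - 1L))
    out
}

allSurjections <- function(k2, k1) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(k1)), k2)))
    keep <- apply(grid, 1L, function(a) length(unique(a)) == k1)
    lapply(which(keep), function(i) as.integer(grid[i, ]))
}
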