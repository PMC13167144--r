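#' Select the anchor mode pair between two K values
#'
#' The anchor pair is the reference through which every other mode at either
#' K is aligned.  Criterion "best" picks the cross-K mode pair with maximal
#' alignment similarity over all pairs (ties: lexicographically smallest mode
#' ID pair); "major" picks the largest mode at each K (M1 under the mode
#' numbering rules, which already break size ties by within-mode similarity
#' and then smallest member run ID).
#'
#' @param modesLow named list of [Mode-class] at the smaller K.
#' @param modesHigh named list of [Mode-class] at the larger K.
#' @param criterion "best" or "major".
#' @return List with `lower`, `upper` (mode IDs) and `alignment` (the direct
#'   cross-K [AlignmentResult-class] of their representatives).
#' @export
selectAnchorPair <- function(modesLow, modesHigh,
                             criterion = c("best", "major")) {
    criterion <- match.arg(criterion)
    if (!length(modesLow) || !length(modesHigh))
        stop("both K levels must have at least one mode")
    if (criterion == "major") {
        lo <- modesLow[[1L]]; hi <- modesHigh[[1L]]
        al <- alignCrossK(representative(lo), representative(hi))
        return(list(lower = modeID(lo), upper = modeID(hi), alignment = al))
    }
    best <- NULL
    for (lo in modesLow) {
        for (hi in modesHigh) {
            al <- alignCrossK(representative(lo), representative(hi))
            cand <- list(lower = modeID(lo), upper = modeID(hi), alignment = al)
            if (is.null(best) ||
                al@similarity > best$alignment@similarity + 1e-12)
                best <- cand
        }
    }
    best
}

#' Align all modes across K values through anchor mode pairs
#'
#' For each adjacent pair of *present* K values (absent K values are skipped
#' and the neighbors aligned directly), the anchor mode pair is aligned
#' cross-K first; every other mode is aligned to the anchor mode of its own K
#' by same-K alignment of representatives, and its cross-K matching is the
#' composition through the anchor's matching.  A consistent global cluster
#' labeling is propagated upward from the smallest K: the major mode at the
#' smallest K defines labels 1..K_min in column order, and each genuinely new
#' cluster gets the next unused label.  When a parent cluster has several
#' children, the child column closest (squared distance) to the parent's
#' column inherits the parent's label; when several new clusters appear at
#' one step (a K gap), new labels are assigned in order of decreasing total
#' membership of the new columns.
#'
#' @param modesByK named list (names are K values, ascending) of named lists
#'   of [Mode-class] objects, as returned by [detectModesByK()] (`$modes`
#'   element) or [summarizeModes()].
#' @param criterion anchor criterion, see [selectAnchorPair()].
#' @return A [ModeAlignmentGraph-class].
#' @export
alignAcrossK <- function(modesByK, criterion = c("best", "major")) {
    criterion <- match.arg(criterion)
    modesByK <- modesByK[order(as.integer(names(modesByK)))]
    kv <- as.integer(names(modesByK))
    if (!length(kv) || !length(modesByK[[1L]])) stop("no modes to align")
    allModes <- list()
    for (lv in modesByK) for (m in lv) allModes[[modeID(m)]] <- m

    labels <- list()
    # base labeling: major mode at smallest K, labels 1..kmin in column order
    baseModes <- modesByK[[1L]]
    baseMajor <- baseModes[[1L]]
    labels[[modeID(baseMajor)]] <- seq_len(modeK(baseMajor))
    for (m in baseModes[-1L]) {
        al <- alignSameK(representative(baseMajor), representative(m))
        labels[[modeID(m)]] <- labels[[modeID(baseMajor)]][al@assignment]
    }
    sameKToAnchor <- function(anchor, lv) {
        out <- list()
        for (m in lv) {
            out[[modeID(m)]] <- if (identical(modeID(m), modeID(anchor)))
                seq_len(modeK(m))
            else alignSameK(representative(anchor), representative(m))@assignment
        }
        out
    }

    anchorPairs <- list()
    edges <- list()
    nextLabel <- max(labels[[modeID(baseMajor)]]) + 1L
    if (length(kv) > 1L) {
        for (step in seq_len(length(kv) - 1L)) {
            k1 <- kv[step]; k2 <- kv[step + 1L]
            lvLow <- modesByK[[step]]; lvHigh <- modesByK[[step + 1L]]
            anchor <- selectAnchorPair(lvLow, lvHigh, criterion)
            anchorPairs[[sprintf("%d-%d", k1, k2)]] <- anchor
            anchLow <- allModes[[anchor$lower]]
            anchHigh <- allModes[[anchor$upper]]
            # sigma maps each mode's local cluster -> its anchor's cluster
            sigLow <- sameKToAnchor(anchLow, lvLow)
            sigHigh <- sameKToAnchor(anchHigh, lvHigh)
            anchAsg <- anchor$alignment@assignment  # anchHigh cluster -> anchLow cluster

            # ---- global labels at the higher K ----
            labLowAnchor <- labels[[anchor$lower]]
            repLow <- memberships(representative(anchLow))
            repHigh <- memberships(representative(anchHigh))
            labHighAnchor <- rep.int(NA_integer_, k2)
            for (d in seq_len(k1)) {
                children <- which(anchAsg == d)
                d2 <- sapply(children,
                             function(c) sum((repHigh[, c] - repLow[, d])^2))
                keep <- children[order(d2, children)][1L]
                labHighAnchor[keep] <- labLowAnchor[d]
            }
            newCols <- which(is.na(labHighAnchor))
            if (length(newCols)) {
                mass <- colSums(repHigh)[newCols]
                for (c in newCols[order(-mass, newCols)]) {
                    labHighAnchor[c] <- nextLabel
                    nextLabel <- nextLabel + 1L
                }
            }
            labels[[anchor$upper]] <- labHighAnchor
            for (m in lvHigh) {
                id <- modeID(m)
                if (identical(id, anchor$upper)) next
                labels[[id]] <- labHighAnchor[sigHigh[[id]]]
            }

            # ---- cross-K edges for every mode pair, composed via the anchor ----
            for (mh in lvHigh) {
                for (ml in lvLow) {
                    idh <- modeID(mh); idl <- modeID(ml)
                    isAnchor <- identical(idh, anchor$upper) &&
                                identical(idl, anchor$lower)
                    asg <- if (isAnchor) anchAsg else {
                        # mh cluster -> anchorHigh cluster -> anchorLow cluster
                        #   -> ml cluster
                        toLow <- anchAsg[sigHigh[[idh]]]
                        invSigLow <- order(sigLow[[idl]])  # anchorLow -> ml
                        invSigLow[toLow]
                    }
                    cost <- alignmentCost(representative(ml),
                                          representative(mh), asg)
                    edges[[paste(idl, idh, sep = "|")]] <- list(
                        lower = idl, upper = idh,
                        alignment = alignmentResult(asg, k2, k1, cost),
                        isAnchor = isAnchor)
                }
            }
        }
    }
    new("ModeAlignmentGraph", modes = allModes, kValues = kv,
        anchorPairs = anchorPairs, edges = edges, clusterLabels = labels)
}

#' Pattern edges of a mode alignment graph
#'
#' One record per (parent cluster -> child cluster) implied by each cross-K
#' matching in the graph.  `isNewClusterEdge` is TRUE iff the child cluster's
#' global label does not exist at the parent's K level (i.e., the child is a
#' newly emerged cluster); `isAnchor` marks edges belonging to the anchor
#' mode pair.  These records drive [plotAlignmentPattern()].
#'
#' @param g a [ModeAlignmentGraph-class].
#' @return A data.frame with columns parentMode, parentLabel, childMode,
#'   childLabel, childCluster (local index), isAnchor, isNewClusterEdge.
#' @export
patternEdges <- function(g) {
    rows <- list()
    # labels present at each K level (union over that level's modes)
    labelsAtK <- lapply(g@kValues, function(k) {
        ids <- names(g@modes)[vapply(g@modes, modeK, integer(1)) == k]
        sort(unique(unlist(g@clusterLabels[ids])))
    })
    names(labelsAtK) <- as.character(g@kValues)
    for (e in g@edges) {
        labLow <- g@clusterLabels[[e$lower]]
        labHigh <- g@clusterLabels[[e$upper]]
        kLow <- modeK(g@modes[[e$lower]])
        present <- labelsAtK[[as.character(kLow)]]
        asg <- e$alignment@assignment
        for (c in seq_along(asg)) {
            rows[[length(rows) + 1L]] <- data.frame(
                parentMode = e$lower, parentLabel = labLow[asg[c]],
                childMode = e$upper, childLabel = labHigh[c],
                childCluster = c,
                isAnchor = e$isAnchor,
                isNewClusterEdge = !(labHigh[c] %in% present),
                stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(parentMode = character(), parentLabel = integer(),
                          childMode = character(), childLabel = integer(),
                          childCluster = integer(), isAnchor = logical(),
                          isNewClusterEdge = logical()))
    do.call(rbind, rows)
}

#' Alignment-pattern text lines
#'
#' One line per cross-K mode pair, "K2M1-K3M1: 1,2,1" style: the 1-based
#' global parent label for each child cluster of the higher-K mode, in local
#' column order.  Anchor pairs are marked with " (anchor)".
#'
#' @param g a [ModeAlignmentGraph-class].
#' @return Character vector of lines.
#' @export
alignmentPatternLines <- function(g) {
    out <- character()
    for (nm in names(g@edges)) {
        e <- g@edges[[nm]]
        labLow <- g@clusterLabels[[e$lower]]
        parents <- labLow[e$alignment@assignment]
        out <- c(out, sprintf("%s-%s: %s%s", e$lower, e$upper,
                              paste(parents, collapse = ","),
                              if (e$isAnchor) " (anchor)" else ""))
    }
    sort(out)
}
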