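helperModesByK <- function(sh, ...) {
    byK <- detectModesByK(sh$collection, ...)
    lapply(byK, `[[`, "modes")
}

test_that("anchor selection honors both criteria", {
    sh <- makeSplitHierarchy(2, 3, syntheticSpec(nIndividuals = 30, k = 2,
                                                 groupSizes = c(15, 15),
                                                 seed = 3),
                             runsPerK = 2)
    modesByK <- helperModesByK(sh)
    # single mode per K: same pair under either criterion
    for (crit in c("best", "major")) {
        ap <- selectAnchorPair(modesByK[["2"]], modesByK[["3"]], crit)
        expect_equal(ap$lower, "K2M1")
        expect_equal(ap$upper, "K3M1")
        expect_equal(ap$alignment@cost, 0, tolerance = 1e-9)
    }
    expect_error(selectAnchorPair(list(), modesByK[["3"]]), "at least one")

    # constructed similarities: "best" takes the max over enumerated pairs
    sim <- twoModeCollection(seed = 20)           # two modes at K = 3
    modes3 <- summarizeModes(runs(sim$collection))
    spec4 <- syntheticSpec(nIndividuals = 60, k = 4, nRuns = 3, seed = 21)
    sim4 <- makeMultimodalCollection(spec4)       # one mode at K = 4
    modes4 <- summarizeModes(runs(sim4$collection))
    best <- selectAnchorPair(modes3, modes4, "best")
    sims <- vapply(modes3, function(m)
        alignCrossK(representative(m), representative(modes4[[1L]]))@similarity,
        numeric(1))
    expect_equal(best$lower, names(modes3)[which.max(sims)])
    major <- selectAnchorPair(modes3, modes4, "major")
    expect_equal(major$lower, "K3M1")
})

test_that("zero-noise split hierarchies align across K with planted structure", {
    spec <- syntheticSpec(nIndividuals = 60, k = 2, groupSizes = c(30, 30),
                          seed = 5)
    sh <- makeSplitHierarchy(2, 6, spec, runsPerK = 3)
    g <- alignAcrossK(helperModesByK(sh), criterion = "best")
    expect_equal(g@kValues, 2:6)
    # every composed cross-K matching of the pure split chain has cost 0
    for (e in g@edges) expect_equal(e$alignment@cost, 0, tolerance = 1e-9)
    # exactly one new label per K step, appended in order
    for (k in 2:6) {
        labs <- g@clusterLabels[[sprintf("K%dM1", k)]]
        expect_setequal(labs, seq_len(k))
    }
    pe <- patternEdges(g)
    newEdges <- pe[pe$isNewClusterEdge, ]
    expect_equal(nrow(newEdges), 4L)
    # each new cluster's parent equals the planted split parent
    expect_equal(newEdges$parentLabel[order(newEdges$childLabel)],
                 sh$splits$parent[order(sh$splits$k)])
    # anchor chain flagged
    expect_true(all(newEdges$isAnchor))
})

test_that("K gaps are aligned directly and introduce K2 - K1 new labels", {
    spec <- syntheticSpec(nIndividuals = 40, k = 2, groupSizes = c(20, 20),
                          seed = 7)
    sh <- makeSplitHierarchy(2, 4, spec, runsPerK = 2, kValues = c(2, 4))
    g <- alignAcrossK(helperModesByK(sh))
    expect_equal(g@kValues, c(2L, 4L))
    expect_length(g@anchorPairs, 1L)
    labs4 <- g@clusterLabels[["K4M1"]]
    expect_setequal(labs4, 1:4)
    pe <- patternEdges(g)
    expect_equal(sum(pe$isNewClusterEdge), 2L)
    # both planted sequential splits recovered across the gap: the two new
    # labels attach to the planted parents (traced through the K=3 plant)
    expect_equal(g@anchorPairs[["2-4"]]$alignment@cost, 0, tolerance = 1e-9)
})

test_that("non-anchor modes are composed consistently through the anchor", {
    # hand-built mode sets: the non-anchor mode at K = 3 is a clean column
    # permutation of the anchor mode, so its composed cross-K matching must
    # equal the direct optimal one
    spec <- syntheticSpec(nIndividuals = 60, k = 3, seed = 9)
    sh <- makeSplitHierarchy(3, 4, spec, runsPerK = 2)
    base3 <- membershipMatrix(sh$bases[["3"]], runID = "K3M1")
    base4 <- membershipMatrix(sh$bases[["4"]], runID = "K4M1")
    perm <- c(2L, 3L, 1L)
    permuted <- membershipMatrix(memberships(base3)[, perm], runID = "K3M2")
    mkMode <- function(id, rep, members, ws = 1) {
        new("Mode", modeID = id, k = nClusters(rep), memberRuns = members,
            representative = rep, withinSimilarity = ws)
    }
    modesByK <- list(
        "3" = list(K3M1 = mkMode("K3M1", base3, c("a.Q", "b.Q")),
                   K3M2 = mkMode("K3M2", permuted, "c.Q")),
        "4" = list(K4M1 = mkMode("K4M1", base4, c("d.Q", "e.Q"))))
    g <- alignAcrossK(modesByK, criterion = "major")
    # the permuted mode's labels are the anchor labels pushed through the
    # permutation; the label multiset is identical
    ids3 <- names(modesByK[["3"]])
    expect_setequal(g@clusterLabels[[ids3[1L]]], g@clusterLabels[[ids3[2L]]])
    # composed matching equals direct brute-force cross-K alignment because
    # the same-K alignment to the anchor is a clean permutation
    other <- setdiff(ids3, vapply(g@anchorPairs, `[[`, character(1), "lower"))
    for (e in g@edges) {
        if (e$lower %in% other) {
            direct <- bruteForceAlign(representative(g@modes[[e$lower]]),
                                      representative(g@modes[[e$upper]]))
            expect_equal(e$alignment@cost, direct@cost, tolerance = 1e-9)
        }
    }
    # label propagation consistency: anchor chains keep labels except new ones
    pe <- patternEdges(g)
    old <- pe[!pe$isNewClusterEdge & pe$isAnchor, ]
    expect_true(all(old$parentLabel == old$childLabel))
})

test_that("alignment pattern text lists parent labels per child cluster", {
    spec <- syntheticSpec(nIndividuals = 30, k = 2, groupSizes = c(15, 15),
                          seed = 2)
    sh <- makeSplitHierarchy(2, 3, spec, runsPerK = 2)
    g <- alignAcrossK(helperModesByK(sh))
    lines <- alignmentPatternLines(g)
    expect_length(lines, 1L)
    expect_match(lines[1L], "^K2M1-K3M1: [0-9]+(,[0-9]+)* \\(anchor\\)$")
    parents <- as.integer(strsplit(sub(" .*$", "",
                                       sub("^.*: ", "", lines[1L])), ",")[[1L]])
    # the split parent appears twice (old child + new child), K2-M1 labels
    expect_length(parents, 3L)
    expect_equal(sort(unique(parents)), 1:2)
})
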