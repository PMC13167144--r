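test_that("similarity networks are symmetric, unit-diagonal and complete", {
    set.seed(2)
    base <- randQ(20, 3, runID = "b")
    reps <- makeReplicates(base, 4, permute = TRUE, noiseScale = 80, seed = 3)
    net <- buildSimilarityNetwork(reps$runs)
    w <- similarityWeights(net)
    expect_equal(w, t(w))
    expect_equal(diag(w), rep(1, 4))
    expect_true(all(w >= 0 & w <= 1 + 1e-9))
    # every off-diagonal pair was computed (replicates of one base: all high)
    expect_true(all(w[upper.tri(w)] > 0.9))

    # identical runs -> all weights 1
    same <- lapply(1:3, function(i) membershipMatrix(memberships(base),
                                                     runID = paste0("r", i)))
    w1 <- similarityWeights(buildSimilarityNetwork(same))
    expect_equal(w1, matrix(1, 3, 3), tolerance = 1e-12)

    one <- buildSimilarityNetwork(list(base))
    expect_equal(dim(similarityWeights(one)), c(1L, 1L))
    expect_error(buildSimilarityNetwork(list(base, randQ(20, 4))), "share K")
})

test_that("planted two-block networks are partitioned into the planted modes", {
    sim <- twoModeCollection(seed = 4)
    net <- buildSimilarityNetwork(runs(sim$collection))
    parts <- detectModes(net, seed = 42)
    expect_equal(lengths(parts), c(6L, 4L))
    got <- parts[[1L]]
    expect_setequal(got, names(sim$modeOf)[sim$modeOf == 1])
    # exact partition: every run in exactly one mode
    expect_setequal(unlist(parts), runIDs(net))
    expect_equal(anyDuplicated(unlist(parts)), 0L)
    # reproducible bit-for-bit under a fixed seed
    expect_identical(parts, detectModes(net, seed = 42))
    # MCL recovers the same planted split
    partsMcl <- detectModes(net, method = "mcl")
    expect_equal(lengths(partsMcl), c(6L, 4L))
    expect_setequal(partsMcl[[1L]], got)
    expect_error(detectModes(net, method = "nope"))
})

test_that("mode extremes behave as the theory states", {
    # identical up to permutation: one mode of size R
    base <- makeBaseMatrix(syntheticSpec(nIndividuals = 30, k = 3, seed = 6))
    reps <- makeReplicates(base, 8, permute = TRUE, noiseScale = Inf, seed = 7)
    net <- buildSimilarityNetwork(reps$runs)
    parts <- detectModes(net, seed = 42)
    expect_length(parts, 1L)
    expect_length(parts[[1L]], 8L)

    # mutually dissimilar runs: R singleton modes
    spec <- syntheticSpec(nIndividuals = 60, k = 6, nRuns = 6, nModes = 6,
                          modeAssignment = 1:6, seed = 8)
    sim <- makeMultimodalCollection(spec)
    net2 <- buildSimilarityNetwork(runs(sim$collection))
    expect_lt(max(similarityWeights(net2)[upper.tri(similarityWeights(net2))]),
              0.7)
    parts2 <- detectModes(net2, seed = 42)
    expect_length(parts2, 6L)
    expect_true(all(lengths(parts2) == 1L))
    parts2m <- detectModes(net2, method = "mcl")
    expect_true(all(lengths(parts2m) == 1L))
})

test_that("forced single mode bypasses community detection at the tolerance", {
    base <- makeBaseMatrix(syntheticSpec(nIndividuals = 20, k = 3, seed = 9))
    reps <- makeReplicates(base, 5, permute = TRUE, noiseScale = Inf, seed = 2)
    net <- buildSimilarityNetwork(reps$runs)
    d <- 1 - similarityWeights(net)
    expect_lt(max(d[upper.tri(d)]), 1e-6)
    parts <- detectModes(net, forceSingleTol = 1e-6, seed = 42)
    expect_length(parts, 1L)
    expect_length(parts[[1L]], 5L)
    # dissimilarity above the tolerance: no bypass
    sim <- twoModeCollection(seed = 10)
    net2 <- buildSimilarityNetwork(runs(sim$collection))
    expect_length(detectModes(net2, forceSingleTol = 1e-6, seed = 42), 2L)
})

test_that("within-mode similarity is the mean over unordered pairs", {
    w <- diag(1, 3)
    w[1, 2] <- w[2, 1] <- 0.9
    w[1, 3] <- w[3, 1] <- 0.8
    w[2, 3] <- w[3, 2] <- 0.7
    net <- new("SimilarityNetwork", weights = w, runIDs = c("a", "b", "c"),
               k = 2L)
    expect_equal(withinModeSimilarity(c("a", "b", "c"), net), 0.8)
    expect_equal(withinModeSimilarity("a", net), 1)     # singleton
    expect_equal(withinModeSimilarity(c("a", "b"), net), 0.9)
    expect_error(withinModeSimilarity("zz", net), "unknown")
})

test_that("mode representatives average aligned members", {
    m1 <- membershipMatrix(rbind(c(0.8, 0.2), c(0.3, 0.7)), runID = "a")
    m2 <- membershipMatrix(rbind(c(0.6, 0.4), c(0.5, 0.5)), runID = "b")
    avg <- modeRepresentative(list(m1, m2))
    expect_equal(memberships(avg), rbind(c(0.7, 0.3), c(0.4, 0.6)),
                 tolerance = 1e-12)
    expect_equal(memberships(modeRepresentative(list(m1))), memberships(m1))
    expect_error(modeRepresentative(list()), "zero members")
    # two members that are column permutations of each other: after
    # alignment the representative equals either one
    m2p <- membershipMatrix(memberships(m1)[, c(2, 1)], runID = "p")
    modes <- summarizeModes(list(m1, m2p))
    expect_length(modes, 1L)
    expect_equal(memberships(representative(modes[[1L]])), memberships(m1),
                 tolerance = 1e-9)
})

test_that("mode numbering follows size, similarity, then run-ID tie-breaks", {
    sim <- twoModeCollection(seed = 12)
    modes <- summarizeModes(runs(sim$collection))
    expect_equal(names(modes), c("K3M1", "K3M2"))
    sizes <- vapply(modes, modeSize, integer(1))
    expect_true(all(diff(sizes) <= 0))
    expect_equal(sizes[["K3M1"]], 6L)
    expect_true(all(vapply(modes, withinSimilarity, numeric(1)) > 0.95))
    # representative rows sum to 1
    for (m in modes)
        expect_equal(rowSums(memberships(representative(m))), rep(1, 60),
                     tolerance = 1e-6)
})
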