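test_that("base matrices honor the planted profiles and determinism", {
    spec <- syntheticSpec(nIndividuals = 1000, k = 2, groupSizes = c(500, 500),
                          profileStrength = 0.9, noiseScale = 50, seed = 3)
    b1 <- makeBaseMatrix(spec)
    b2 <- makeBaseMatrix(spec)
    expect_identical(memberships(b1), memberships(b2))   # seeded determinism
    # law of large numbers: group mean within 0.02 of the (0.9, 0.1) profile
    g1 <- colMeans(memberships(b1)[1:500, ])
    expect_lt(max(abs(g1 - c(0.9, 0.1))), 0.02)
    # degenerate Dirichlet limit: rows equal profiles exactly
    specInf <- syntheticSpec(nIndividuals = 10, k = 2, groupSizes = c(5, 5),
                             noiseScale = Inf, profileStrength = 0.9, seed = 1)
    bInf <- makeBaseMatrix(specInf)
    expect_equal(memberships(bInf)[1, ], c(0.9, 0.1), tolerance = 1e-12)
    expect_error(syntheticSpec(nIndividuals = 10, k = 2,
                               groupSizes = c(4, 3, 3)), "distinct dominant")
    # generated matrices satisfy the container invariants
    expect_true(validObject(b1))
})

test_that("replicates carry recoverable planted permutations", {
    spec <- syntheticSpec(nIndividuals = 40, k = 4, seed = 5)
    base <- makeBaseMatrix(spec)
    # zero noise: every planted permutation recovered with cost 0
    reps <- makeReplicates(base, 6, permute = TRUE, noiseScale = Inf, seed = 6)
    for (r in seq_along(reps$runs)) {
        al <- alignSameK(base, reps$runs[[r]])
        expect_equal(al@cost, 0, tolerance = 1e-12)
        expect_identical(al@assignment, as.integer(reps$perms[[r]]))
    }
    # zero noise, no permutation: all pairwise similarities 1
    reps0 <- makeReplicates(base, 4, permute = FALSE, noiseScale = Inf,
                            seed = 7)
    w <- similarityWeights(buildSimilarityNetwork(reps0$runs))
    expect_equal(w, matrix(1, 4, 4), tolerance = 1e-12)
    # determinism
    repsA <- makeReplicates(base, 3, noiseScale = 50, seed = 8)
    repsB <- makeReplicates(base, 3, noiseScale = 50, seed = 8)
    expect_identical(lapply(repsA$runs, memberships),
                     lapply(repsB$runs, memberships))
})

test_that("multimodal collections separate planted modes as designed", {
    sim <- twoModeCollection(seed = 40)
    w <- similarityWeights(buildSimilarityNetwork(runs(sim$collection)))
    same <- outer(sim$modeOf, sim$modeOf, "==")
    expect_gt(min(w[same & upper.tri(w)]), 0.95)
    expect_lt(max(w[!same & upper.tri(w)]), 0.6)
    # single planted mode: one detected mode
    one <- makeMultimodalCollection(
        syntheticSpec(nIndividuals = 30, k = 3, nRuns = 5, seed = 41))
    parts <- detectModes(buildSimilarityNetwork(runs(one$collection)))
    expect_length(parts, 1L)
})

test_that("split hierarchies plant exact parent-child structure", {
    spec <- syntheticSpec(nIndividuals = 30, k = 2, groupSizes = c(15, 15),
                          seed = 44)
    sh <- makeSplitHierarchy(2, 5, spec, runsPerK = 2)
    expect_equal(sh$splits$k, 3:5)
    for (i in seq_len(nrow(sh$splits))) {
        k <- sh$splits$k[i]
        parentBase <- membershipMatrix(sh$bases[[as.character(k - 1L)]])
        childBase <- membershipMatrix(sh$bases[[as.character(k)]])
        al <- alignCrossK(parentBase, childBase)
        expect_equal(al@cost, 0, tolerance = 1e-12)
        expect_equal(al@assignment[sh$splits$child2[i]], sh$splits$parent[i])
        expect_equal(al@assignment[sh$splits$child1[i]], sh$splits$parent[i])
    }
    # all matrices valid and deterministic
    sh2 <- makeSplitHierarchy(2, 5, spec, runsPerK = 2)
    expect_identical(lapply(runs(sh$collection), memberships),
                     lapply(runs(sh2$collection), memberships))
    expect_error(makeSplitHierarchy(3, 3, spec), "kMin")
})

test_that("fixture directories round-trip through the standard .Q dialect", {
    dir <- file.path(withr::local_tempdir(), "fix")
    sim <- twoModeCollection(seed = 50, nRuns = 4,
                             modeAssignment = c(1L, 1L, 2L, 2L))
    writeCollection(sim$collection, dir,
                    plants = list(mode_of = as.list(sim$modeOf)))
    expect_true(file.exists(file.path(dir, "plants.json")))
    coll <- loadRunCollection(dir, labels = file.path(dir, "labels.txt"))
    expect_length(runs(coll), 4L)
    expect_equal(lapply(runs(coll), memberships),
                 lapply(runs(sim$collection), memberships),
                 tolerance = 1e-12)
})
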