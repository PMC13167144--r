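test_that("alignment cost matches hand computations and identities", {
    qa <- membershipMatrix(rbind(c(0.6, 0.4), c(0.1, 0.9)))
    qb <- membershipMatrix(rbind(c(0.5, 0.5), c(0.3, 0.7)))
    # (0.01 + 0.01 + 0.04 + 0.04) / (2 * 2)
    expect_equal(alignmentCost(qa, qb, c(1, 2)), 0.025, tolerance = 1e-12)

    # identical runs, identity matching
    expect_equal(alignmentCost(qa, qa, c(1, 2)), 0)

    # maximal single-row distance: N=1, disjoint unit rows
    q1 <- membershipMatrix(matrix(c(1, 0), 1))
    q2 <- membershipMatrix(matrix(c(0, 1), 1))
    expect_equal(alignmentCost(q1, q2, c(1, 2)), 1)

    expect_error(alignmentCost(qa, qb, c(1, 1)), "surjective")
})

test_that("equal-K alignment recovers permutations and trivial cases", {
    set.seed(21)
    qa <- randQ(8, 4)
    p <- c(3, 1, 4, 2)
    qb <- membershipMatrix(memberships(qa)[, p])  # column j of qb is qa col p[j]
    al <- alignSameK(qa, qb)
    expect_equal(al@cost, 0, tolerance = 1e-12)
    expect_equal(al@similarity, 1, tolerance = 1e-12)
    expect_identical(al@assignment, as.integer(p))

    # K = 1: unique trivial matching
    k1 <- membershipMatrix(matrix(1, 3))
    al1 <- alignSameK(k1, k1)
    expect_identical(al1@assignment, 1L)
    expect_equal(al1@cost, 0)

    expect_error(alignSameK(randQ(4, 2), randQ(4, 3)), "alignCrossK")
})

test_that("equal-K and cross-K solvers agree with the brute-force oracle", {
    set.seed(99)
    for (i in 1:40) {
        k <- sample(2:6, 1)
        qa <- randQ(sample(2:12, 1) -> n, k); qb <- randQ(n, k)
        fast <- alignSameK(qa, qb)
        slow <- bruteForceAlign(qa, qb)
        expect_equal(fast@cost, slow@cost, tolerance = 1e-9)
        expect_identical(fast@assignment, slow@assignment)
    }
    for (i in 1:30) {
        k1 <- sample(2:4, 1); k2 <- k1 + sample(1:2, 1)
        n <- sample(2:10, 1)
        qa <- randQ(n, k1); qb <- randQ(n, k2)
        fast <- alignCrossK(qa, qb)
        slow <- bruteForceAlign(qa, qb)
        expect_equal(fast@cost, slow@cost, tolerance = 1e-9)
        expect_identical(fast@assignment, slow@assignment)
    }
})

test_that("cross-K alignment maps a clean column split back with cost 0", {
    set.seed(5)
    qs <- randQ(10, 3)
    m <- memberships(qs)
    # split column 2 into two children summing to it
    w <- runif(10, 0.3, 0.7)
    big <- cbind(m[, 1], w * m[, 2], m[, 3], (1 - w) * m[, 2])
    ql <- membershipMatrix(big)
    al <- alignCrossK(qs, ql)
    expect_equal(al@cost, 0, tolerance = 1e-12)
    expect_identical(al@assignment, c(1L, 2L, 3L, 2L))

    # an all-zero source column never perturbs the rest of the optimum
    ql0 <- membershipMatrix(cbind(m, 0), normalize = FALSE)
    al0 <- alignCrossK(qs, ql0)
    slow <- bruteForceAlign(qs, ql0)
    expect_equal(al0@cost, slow@cost, tolerance = 1e-9)
    expect_equal(al0@cost, 0, tolerance = 1e-12)

    expect_error(alignCrossK(randQ(4, 3), randQ(4, 3)), "alignSameK")
    expect_error(bruteForceAlign(randQ(3, 2), randQ(3, 8)), "K > 7")
})

test_that("optimal cost is symmetric, bounded, and permutation-invariant", {
    set.seed(31)
    for (i in 1:15) {
        k <- sample(2:5, 1); n <- sample(3:10, 1)
        qa <- randQ(n, k); qb <- randQ(n, k)
        ab <- alignSameK(qa, qb); ba <- alignSameK(qb, qa)
        expect_equal(ab@cost, ba@cost, tolerance = 1e-9)
        expect_gte(ab@cost, 0); expect_lte(ab@cost, 1)
        expect_equal(ab@similarity, 1 - ab@cost, tolerance = 1e-12)
        # permuting either input's columns leaves the optimum unchanged
        p <- sample(k)
        qbp <- membershipMatrix(memberships(qb)[, p])
        expect_equal(alignSameK(qa, qbp)@cost, ab@cost, tolerance = 1e-9)
        qap <- membershipMatrix(memberships(qa)[, p])
        expect_equal(alignSameK(qap, qb)@cost, ab@cost, tolerance = 1e-9)
    }
    for (i in 1:10) {
        n <- sample(3:8, 1)
        qa <- randQ(n, 2); qb <- randQ(n, 4)
        base <- alignCrossK(qa, qb)@cost
        p <- sample(4)
        qbp <- membershipMatrix(memberships(qb)[, p])
        expect_equal(alignCrossK(qa, qbp)@cost, base, tolerance = 1e-9)
    }
})

test_that("applyMatching permutes or merges columns as the cost defines", {
    set.seed(8)
    q <- randQ(5, 4)
    perm <- c(2L, 4L, 1L, 3L)
    out <- applyMatching(q, perm, 4L)
    expect_equal(memberships(out)[, 2], memberships(q)[, 1])
    merged <- applyMatching(q, c(1L, 1L, 2L, 2L), 2L)
    expect_equal(memberships(merged)[, 1],
                 rowSums(memberships(q)[, 1:2]))
    expect_equal(rowSums(memberships(merged)), rep(1, 5), tolerance = 1e-9)
})

test_that("a K = 40 alignment solves in well under a second", {
    set.seed(1)
    qa <- randQ(200, 40)
    qb <- membershipMatrix(memberships(qa)[, sample(40)])
    t0 <- proc.time()[["elapsed"]]
    al <- alignSameK(qa, qb)
    expect_lt(proc.time()[["elapsed"]] - t0, 5)
    expect_equal(al@cost, 0, tolerance = 1e-9)
})
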