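test_that("admixture .Q files parse, renormalize drift, and reject bad input", {
    f <- withr::local_tempfile(fileext = ".Q")
    writeLines(c("0.6 0.4", "0.1 0.9"), f)
    q <- readAdmixtureQ(f)
    expect_equal(memberships(q), rbind(c(0.6, 0.4), c(0.1, 0.9)))
    expect_equal(nClusters(q), 2L)
    expect_equal(nIndividuals(q), 2L)

    # drifted row is renormalized as x / sum(x)
    writeLines("0.60 0.39", f)
    q2 <- readAdmixtureQ(f)
    expect_equal(memberships(q2)[1, ], c(0.60 / 0.99, 0.39 / 0.99),
                 tolerance = 1e-12)

    writeLines(c("0.6 0.4", "0.1 0.2 0.7"), f)
    expect_error(readAdmixtureQ(f), "ragged")
    writeLines(c("0.6 -0.1"), f)
    expect_error(readAdmixtureQ(f), "negative")
    writeLines(c("0.6 0.6"), f)   # 20% drift: beyond repair
    expect_error(readAdmixtureQ(f), "drift")
})

test_that("structure run files yield the same matrix as the .Q dialect", {
    set.seed(42)
    q <- round(memberships(randQ(3, 2)), 4)
    q <- q / rowSums(q)
    fs <- withr::local_tempfile(fileext = ".txt")
    writeStructureFixture(fs, q)
    m1 <- readStructureRun(fs)
    expect_equal(dim(memberships(m1)), c(3L, 2L))

    fq <- withr::local_tempfile(fileext = ".Q")
    writeQ(q, fq)
    m2 <- readAdmixtureQ(fq)
    expect_equal(memberships(m1), memberships(m2), tolerance = 1e-12)

    # truncated block: fewer rows than the declared individual count
    lines <- readLines(fs)
    writeLines(lines[-8L], fs)
    expect_error(readStructureRun(fs), "truncated")
    writeLines("no block here", fs)
    expect_error(readStructureRun(fs), "not found")
})

test_that("collections load deterministically, grouped by K, with N checks", {
    dir <- withr::local_tempdir()
    set.seed(7)
    for (k in 2:3)
        for (r in 1:3)
            writeQ(memberships(randQ(5, k)),
                   file.path(dir, sprintf("K%d_run%d.Q", k, r)))
    coll <- loadRunCollection(dir)
    expect_s4_class(coll, "RunCollection")
    byK <- runsByK(coll)
    expect_equal(names(byK), c("2", "3"))
    expect_equal(lengths(byK), c("2" = 3L, "3" = 3L))
    # lexicographic order by filename
    expect_equal(vapply(runs(coll), runID, character(1)),
                 sort(vapply(runs(coll), runID, character(1))))
    # same listing, same order
    coll2 <- loadRunCollection(dir)
    expect_identical(vapply(runs(coll2), runID, character(1)),
                     vapply(runs(coll), runID, character(1)))

    writeQ(memberships(randQ(7, 2)), file.path(dir, "badN.Q"))
    expect_error(loadRunCollection(dir), "badN")
    unlink(file.path(dir, list.files(dir)))
    expect_error(loadRunCollection(dir), "no run files")
})

test_that("single-file collections and label files load", {
    dir <- withr::local_tempdir()
    writeQ(rbind(c(0.7, 0.3), c(0.2, 0.8)), file.path(dir, "one.Q"))
    writeLines(c("popA", "popB"), file.path(dir, "labels.txt"))
    coll <- loadRunCollection(dir, labels = file.path(dir, "labels.txt"))
    expect_length(runs(coll), 1L)
    expect_equal(popLabels(coll)@groupOrder, c("popA", "popB"))
})

test_that("writing relabeled matrices round-trips and honors the relabeling", {
    f1 <- withr::local_tempfile(fileext = ".Q")
    f2 <- withr::local_tempfile(fileext = ".Q")
    f3 <- withr::local_tempfile(fileext = ".Q")
    set.seed(3)
    q <- randQ(4, 3)
    writeQ(memberships(q), f1)
    p1 <- readAdmixtureQ(f1)

    # identity relabeling: content unchanged
    writeAlignedQ(p1, path = f2)
    expect_equal(memberships(readAdmixtureQ(f2)), memberships(p1),
                 tolerance = 1e-12)

    # 3-column cyclic relabeling on a 2x3 matrix, applied by hand:
    # relabeling c(2,3,1) sends column 1 -> slot 2, 2 -> 3, 3 -> 1
    m <- membershipMatrix(rbind(c(0.5, 0.3, 0.2), c(0.1, 0.6, 0.3)))
    writeAlignedQ(m, c(2, 3, 1), f3)
    expect_equal(memberships(readAdmixtureQ(f3, runID = "cyc")),
                 rbind(c(0.2, 0.5, 0.3), c(0.3, 0.1, 0.6)),
                 tolerance = 1e-12)

    # swap applied twice restores the file content
    writeAlignedQ(p1, c(2, 1, 3), f2)
    writeAlignedQ(readAdmixtureQ(f2), c(2, 1, 3), f3)
    expect_identical(readLines(f3), readLines(f1))

    expect_error(writeAlignedQ(p1, c(1, 2), f2), "permutation")
})

test_that("parse-write-parse round trip is exact to 1e-12 and rows sum to 1", {
    set.seed(11)
    f <- withr::local_tempfile(fileext = ".Q")
    g <- withr::local_tempfile(fileext = ".Q")
    for (i in 1:5) {
        writeQ(memberships(randQ(6, 4)), f)
        p1 <- readAdmixtureQ(f)
        writeAlignedQ(p1, path = g)
        p2 <- readAdmixtureQ(g)
        expect_equal(memberships(p2), memberships(p1), tolerance = 1e-12)
        expect_equal(rowSums(memberships(p1)), rep(1, 6), tolerance = 1e-6)
    }
})
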