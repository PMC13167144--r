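# shared fixture builders (all programmatic; no stored data)

# random row-stochastic N x K matrix
randQ <- function(n, k, runID = "run") {
    m <- matrix(stats::rgamma(n * k, shape = 1), n, k)
    membershipMatrix(m / rowSums(m), runID = runID)
}

# write a .Q file from a plain matrix
writeQ <- function(m, path) {
    writeLines(apply(m, 1L, function(r) paste(sprintf("%.15g", r),
                                              collapse = " ")), path)
    path
}

# a minimal Structure-style run file with the membership block
writeStructureFixture <- function(path, q, popcol = 1L) {
    n <- nrow(q)
    lines <- c(
        "STRUCTURE by Pritchard, Stephens and Donnelly",
        sprintf("%d individuals", n),
        sprintf("%d populations assumed", ncol(q)),
        "",
        "Inferred ancestry of individuals:",
        "        Label (%Miss) Pop:  Inferred clusters",
        vapply(seq_len(n), function(i) {
            sprintf("%3d %6s  (0)  %d 	:  %s", i, sprintf("ind%d", i), popcol,
                    paste(sprintf("%.4f", q[i, ]), collapse = " "))
        }, character(1)),
        "",
        "Estimated Allele Frequencies in each cluster")
    writeLines(lines, path)
    path
}

# collection with two planted modes (6 + 4 runs), well separated
twoModeCollection <- function(seed = 1L, nRuns = 10L,
                              modeAssignment = c(rep(1L, 6), rep(2L, 4))) {
    spec <- syntheticSpec(nIndividuals = 60, k = 3, nRuns = nRuns, nModes = 2,
                          modeAssignment = modeAssignment, seed = seed)
    makeMultimodalCollection(spec)
}
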