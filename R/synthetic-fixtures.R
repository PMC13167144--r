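#' Specification for synthetic replicate membership matrices
#'
#' Describes a planted study: labeled population groups, each with a
#' distinct dominant-cluster profile; replicate runs drawn from per-row
#' Dirichlet noise around the profiles; optional planted alternative modes
#' and per-run column permutations.  All generation is deterministic under
#' the seed.
#'
#' The Dirichlet concentration for a row with base profile p is
#' `noiseScale * p`, so draws stay on the simplex and `noiseScale -> Inf`
#' recovers the profile exactly.  The default `noiseScale = 50` gives
#' within-run jitter of roughly 0.01-0.05 per coefficient — comparable to
#' replicate scatter of a well-converged ADMIXTURE run.
#'
#' @param nIndividuals total N.
#' @param groupSizes per-group counts summing to N (default: near-equal
#'   groups, one per cluster).
#' @param k number of clusters.
#' @param nRuns number of replicate runs.
#' @param nModes number of planted modes (>= 1).
#' @param modeAssignment integer vector (length nRuns) mapping run -> mode;
#'   default splits runs evenly, larger modes first.
#' @param noiseScale Dirichlet concentration multiplier.
#' @param profileStrength dominant-cluster membership of each group profile
#'   (default 0.95; the remainder is spread evenly).
#' @param reassignFraction fraction of each group's individuals whose
#'   dominant cluster is cyclically shifted in the alternative modes
#'   (default 0.5; this makes planted modes non-equivalent under any label
#'   permutation, with cross-mode optimal similarity around 0.55).
#' @param seed RNG seed.
#' @return A list of class "SyntheticSpec".
#' @export
syntheticSpec <- function(nIndividuals = 60L, k = 3L,
                          groupSizes = NULL, nRuns = 10L, nModes = 1L,
                          modeAssignment = NULL, noiseScale = 50,
                          profileStrength = 0.95, reassignFraction = 0.5,
                          seed = 1L) {
    if (is.null(groupSizes)) {
        g <- k
        groupSizes <- rep(nIndividuals %/% g, g)
        groupSizes[seq_len(nIndividuals %% g)] <-
            groupSizes[seq_len(nIndividuals %% g)] + 1L
    }
    if (sum(groupSizes) != nIndividuals)
        stop("groupSizes must sum to nIndividuals")
    if (length(groupSizes) > k)
        stop("cannot give each of ", length(groupSizes),
             " groups a distinct dominant cluster with k = ", k)
    if (is.null(modeAssignment)) {
        modeAssignment <- sort(rep_len(seq_len(nModes), nRuns))
    }
    if (length(modeAssignment) != nRuns || max(modeAssignment) > nModes)
        stop("modeAssignment must map each of nRuns runs to a mode <= nModes")
    if (nModes > nRuns) stop("nModes must not exceed nRuns")
    structure(list(nIndividuals = as.integer(nIndividuals), k = as.integer(k),
                   groupSizes = as.integer(groupSizes),
                   nRuns = as.integer(nRuns), nModes = as.integer(nModes),
                   modeAssignment = as.integer(modeAssignment),
                   noiseScale = noiseScale,
                   profileStrength = profileStrength,
                   reassignFraction = reassignFraction,
                   seed = as.integer(seed)),
              class = "SyntheticSpec")
}

# per-individual base profile matrix for one planted mode: group g's
# dominant cluster is g for mode 1; in mode m a leading fraction of each
# group is shifted to cluster (g - 1 + m - 1) mod k + 1
modeProfiles <- function(spec, mode = 1L) {
    k <- spec$k
    s <- spec$profileStrength
    off <- (1 - s) / max(1L, k - 1L)
    prof <- matrix(off, spec$nIndividuals, k)
    row <- 0L
    for (g in seq_along(spec$groupSizes)) {
        ng <- spec$groupSizes[g]
        nShift <- if (mode == 1L) 0L else ceiling(spec$reassignFraction * ng)
        for (i in seq_len(ng)) {
            dom <- if (i <= nShift) ((g - 1L + mode - 1L) %% k) + 1L else g
            prof[row + i, ] <- off
            prof[row + i, dom] <- s
        }
        row <- row + ng
    }
    if (k == 1L) prof[] <- 1
    prof
}

#' Planted base membership matrix
#'
#' Each population group gets a distinct dominant-cluster profile; rows are
#' drawn from a Dirichlet centered on the group profile with concentration
#' `noiseScale * profile`.  Deterministic under `spec$seed`.
#'
#' @param spec a [syntheticSpec()].
#' @param mode which planted mode's profile set to use.
#' @return A [MembershipMatrix-class].
#' @export
makeBaseMatrix <- function(spec, mode = 1L) {
    prof <- modeProfiles(spec, mode)
    vals <- if (is.finite(spec$noiseScale)) {
        withSeed(spec$seed + 7919L * (mode - 1L),
                 rdirichletRows(spec$noiseScale * prof))
    } else prof
    membershipMatrix(vals, runID = sprintf("base_m%d", mode))
}

#' Replicates of a base matrix with planted permutations
#'
#' Each replicate applies per-row Dirichlet noise around the base and then a
#' recorded random column permutation (the label-switching model: each of
#' the K! permutations equally likely).  Column j of replicate r holds base
#' cluster `perms[[r]][j]`.
#'
#' @param base a [MembershipMatrix-class].
#' @param nRuns number of replicates.
#' @param permute apply random column permutations (default TRUE).
#' @param noiseScale Dirichlet concentration multiplier (Inf = no noise).
#' @param seed RNG seed.
#' @param prefix run-ID prefix.
#' @return List with `runs` (list of [MembershipMatrix-class]) and `perms`
#'   (list of planted permutations; `perms[[r]][j]` is the base cluster
#'   stored in column j of run r).
#' @export
makeReplicates <- function(base, nRuns, permute = TRUE, noiseScale = 50,
                           seed = 1L, prefix = "run") {
    q0 <- memberships(base)
    k <- ncol(q0)
    withSeed(seed, {
        runsOut <- vector("list", nRuns)
        perms <- vector("list", nRuns)
        for (r in seq_len(nRuns)) {
            q <- if (is.finite(noiseScale))
                rdirichletRows(noiseScale * q0) else q0
            p <- if (permute && k > 1L) sample.int(k) else seq_len(k)
            perms[[r]] <- p
            runsOut[[r]] <- membershipMatrix(
                q[, p, drop = FALSE],
                runID = sprintf("%s_%03d.Q", prefix, r))
        }
        list(runs = runsOut, perms = perms)
    })
}

#' Multimodal synthetic collection with planted mode labels
#'
#' Builds `spec$nModes` distinct base matrices (see [syntheticSpec()]:
#' alternative modes shift the dominant cluster of a fraction of each group,
#' so no label permutation maps one mode onto another) and draws the
#' replicates assigned to each mode by `spec$modeAssignment`.
#'
#' @param spec a [syntheticSpec()].
#' @param permute permute columns of each replicate (default TRUE).
#' @return List with `collection` ([RunCollection-class]), `modeOf` (named
#'   integer vector: run ID -> planted mode), and `perms`.
#' @export
makeMultimodalCollection <- function(spec, permute = TRUE) {
    groups <- rep(seq_along(spec$groupSizes), spec$groupSizes)
    labels <- populationLabels(sprintf("pop%d", groups))
    runsOut <- vector("list", spec$nRuns)
    perms <- vector("list", spec$nRuns)
    modeOf <- integer(spec$nRuns)
    idx <- 0L
    for (m in seq_len(spec$nModes)) {
        which_r <- which(spec$modeAssignment == m)
        if (!length(which_r)) next
        base <- membershipMatrix(modeProfiles(spec, m),
                                 runID = sprintf("base_m%d", m))
        reps <- makeReplicates(base, length(which_r), permute = permute,
                               noiseScale = spec$noiseScale,
                               seed = spec$seed + 104729L * m,
                               prefix = sprintf("m%d", m))
        for (i in seq_along(which_r)) {
            r <- which_r[i]
            runsOut[[r]] <- reps$runs[[i]]
            perms[[r]] <- reps$perms[[i]]
            modeOf[r] <- m
        }
    }
    ids <- vapply(runsOut, runID, character(1))
    names(modeOf) <- ids
    names(perms) <- ids
    list(collection = runCollection(runsOut, labels = labels),
         modeOf = modeOf, perms = perms)
}

#' Split hierarchy across K with planted parent-child records
#'
#' The base at `kMin` comes from the spec profiles; each K + 1 base equals
#' the K base with one recorded column split into two children (weights w
#' and 1 - w of the parent column, w = 0.55, child 1 replacing the parent
#' column, child 2 appended on the right).  Replicates at each K are drawn
#' with [makeReplicates()].  With zero noise and no permutation all cross-K
#' alignments have cost 0 and the planted splits are exactly recoverable.
#'
#' @param kMin,kMax K range (kMin < kMax).
#' @param spec a [syntheticSpec()] (its `k` is ignored; `kMin` is used).
#' @param runsPerK replicates per K value.
#' @param noiseScale,permute replicate options.
#' @param kValues optional subset of kMin:kMax to generate (gap scenarios).
#' @return List with `collection`, `splits` (data.frame: k of the child
#'   level, parent column index in the parent base, child1, child2 column
#'   indices in the child base), `bases` and `perms`.
#' @export
makeSplitHierarchy <- function(kMin, kMax, spec, runsPerK = 5L,
                               noiseScale = Inf, permute = FALSE,
                               kValues = seq(kMin, kMax)) {
    if (kMin >= kMax) stop("kMin must be < kMax")
    if (length(spec$groupSizes) > kMin)
        stop("need k >= number of groups at the lowest level: reduce groups ",
             "or raise kMin")
    specBase <- spec
    specBase$k <- as.integer(kMin)
    base <- modeProfiles(specBase, 1L)
    bases <- list()
    bases[[as.character(kMin)]] <- base
    splits <- list()
    w <- 0.55
    withSeed(spec$seed, {
        for (k in seq(kMin + 1L, kMax)) {
            prev <- bases[[as.character(k - 1L)]]
            parent <- which.max(colSums(prev))  # deterministic split choice
            child1 <- w * prev[, parent]
            child2 <- (1 - w) * prev[, parent]
            nxt <- prev
            nxt[, parent] <- child1
            nxt <- cbind(nxt, child2)
            bases[[as.character(k)]] <- nxt
            splits[[length(splits) + 1L]] <- data.frame(
                k = k, parent = parent, child1 = parent, child2 = k)
        }
    })
    runsOut <- list()
    perms <- list()
    for (k in kValues) {
        b <- membershipMatrix(bases[[as.character(k)]],
                              runID = sprintf("base_K%d", k))
        reps <- makeReplicates(b, runsPerK, permute = permute,
                               noiseScale = noiseScale,
                               seed = spec$seed + 31L * k,
                               prefix = sprintf("K%d", k))
        runsOut <- c(runsOut, reps$runs)
        perms <- c(perms, reps$perms)
    }
    groups <- rep(seq_along(spec$groupSizes), spec$groupSizes)
    list(collection = runCollection(runsOut,
                                    labels = populationLabels(
                                        sprintf("pop%d", groups))),
         splits = do.call(rbind, splits), bases = bases, perms = perms)
}

#' Write a collection as a .Q directory with a JSON plant sidecar
#'
#' Fixture directories use the standard ADMIXTURE .Q dialect so the pipeline
#' and tests share one input path; planted ground truth (if any) is written
#' as `plants.json`.
#'
#' @param collection a [RunCollection-class].
#' @param dir output directory (created if needed).
#' @param plants optional list serialized to `plants.json`.
#' @return `dir`, invisibly.
#' @export
writeCollection <- function(collection, dir, plants = NULL) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (r in runs(collection)) {
        f <- runID(r)
        if (!grepl("\\.q$", f, ignore.case = TRUE)) f <- paste0(f, ".Q")
        writeQFile(memberships(r), file.path(dir, f))
    }
    if (!is.null(popLabels(collection)))
        writeLines(popLabels(collection)@labels, file.path(dir, "labels.txt"))
    if (!is.null(plants))
        jsonlite::write_json(plants, file.path(dir, "plants.json"),
                             auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
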