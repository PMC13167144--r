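#' Read an ADMIXTURE .Q (or fastStructure .meanQ) membership file
#'
#' Both formats are headerless whitespace-delimited matrices with one
#' individual per row and one cluster per column.  K is inferred from the
#' column count.  Rows are validated and renormalized: per-row drift of the
#' sum from 1 up to 0.05 is repaired silently (rounding drift in program
#' output); larger drift or negative entries raise an error.
#'
#' @param path path to the file.
#' @param runID run identifier; defaults to the file name.
#' @param modelID optional model tag.
#' @return A [MembershipMatrix-class].
#' @examples
#' f <- tempfile(fileext = ".Q")
#' writeLines(c("0.6 0.4", "0.1 0.9"), f)
#' readAdmixtureQ(f)
#' @export
readAdmixtureQ <- function(path, runID = basename(path),
                           modelID = NA_character_) {
    if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop(sprintf("'%s' contains no data rows", path))
    fields <- strsplit(trimws(lines), "[ \t]+")
    len <- lengths(fields)
    if (length(unique(len)) != 1L) {
        bad <- which(len != len[1L])[1L]
        stop(sprintf("ragged rows in '%s': line %d has %d fields, expected %d",
                     path, bad, len[bad], len[1L]))
    }
    vals <- suppressWarnings(
        matrix(as.numeric(unlist(fields)), nrow = length(fields), byrow = TRUE))
    if (anyNA(vals)) {
        bad <- which(apply(is.na(vals), 1L, any))[1L]
        stop(sprintf("non-numeric entry in '%s' at line %d", path, bad))
    }
    if (any(vals < 0)) stop(sprintf("negative membership coefficient in '%s'", path))
    membershipMatrix(vals, runID = runID, modelID = modelID)
}

#' @rdname readAdmixtureQ
#' @export
readFastStructureQ <- function(path, runID = basename(path),
                               modelID = NA_character_) {
    readAdmixtureQ(path, runID = runID, modelID = modelID)
}

#' Read the membership block of a Structure run output file
#'
#' Extracts the "Inferred ancestry of individuals" block.  Each individual
#' line carries metadata columns, a colon, then the K membership
#' coefficients; only the columns after the colon are used.
#'
#' @inheritParams readAdmixtureQ
#' @return A [MembershipMatrix-class].
#' @export
readStructureRun <- function(path, runID = basename(path),
                             modelID = NA_character_) {
    if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
    lines <- readLines(path, warn = FALSE)
    start <- grep("Inferred ancestry of individuals", lines, fixed = TRUE)
    if (!length(start))
        stop(sprintf("'%s': 'Inferred ancestry of individuals' block not found",
                     path))
    i <- start[1L] + 1L
    # optional header line ("Label (%Miss) Pop:  Inferred clusters")
    rows <- list()
    declared <- NA_integer_
    while (i <= length(lines)) {
        ln <- trimws(lines[i])
        i <- i + 1L
        if (!nzchar(ln)) {
            if (length(rows)) break else next
        }
        if (!grepl(":", ln, fixed = TRUE)) {
            if (length(rows)) break else next  # header line before data
        }
        after <- sub("^[^:]*:", "", ln)
        # Structure may append per-population credible intervals after the
        # memberships; keep only leading numeric fields
        toks <- strsplit(trimws(after), "[ \t]+")[[1L]]
        num <- suppressWarnings(as.numeric(toks))
        bad <- which(is.na(num))
        vals <- if (length(bad)) num[seq_len(bad[1L] - 1L)] else num
        if (!length(vals)) {
            # header line ("...Pop:  Inferred clusters") before the data
            if (length(rows)) break else next
        }
        rows[[length(rows) + 1L]] <- vals
    }
    if (!length(rows))
        stop(sprintf("'%s': membership block is empty", path))
    len <- lengths(rows)
    if (length(unique(len)) != 1L)
        stop(sprintf("'%s': membership block is ragged or truncated", path))
    # cross-check against the declared number of individuals when present
    decl <- regmatches(lines, regexpr("^\\s*\\d+ individuals", lines))
    decl <- decl[nzchar(decl)]
    if (length(decl)) {
        n_decl <- as.integer(sub("\\s*individuals", "", decl[1L]))
        if (!is.na(n_decl) && n_decl != length(rows))
            stop(sprintf("'%s': block truncated (%d of %d declared individuals)",
                         path, length(rows), n_decl))
    }
    vals <- do.call(rbind, rows)
    if (any(vals < 0)) stop(sprintf("negative membership coefficient in '%s'", path))
    membershipMatrix(vals, runID = runID, modelID = modelID)
}

#' Read a population label file
#'
#' Plain text, one label per line, N lines in individual (row) order.
#'
#' @param path file path.
#' @return A [PopulationLabels-class].
#' @export
readPopulationLabels <- function(path) {
    if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
    labs <- trimws(readLines(path, warn = FALSE))
    labs <- labs[nzchar(labs)]
    populationLabels(labs)
}

#' Load a directory of replicate membership matrices
#'
#' Reads every parseable run file in `dir`, groups runs by K (inferred per
#' file from its column count) and returns a [RunCollection-class].  Files
#' are loaded in lexicographic filename order so load order is deterministic;
#' the filename becomes the run ID.
#'
#' @param dir directory containing the run files.
#' @param format "admixture" (.Q), "faststructure" (.meanQ), "structure"
#'   (Structure run output), or "auto" (by file extension: .Q/.meanQ read as
#'   matrices, anything else attempted as a Structure run file).
#' @param labels optional path to a label file, or a
#'   [PopulationLabels-class].
#' @param modelID optional model tag applied to every run.
#' @param pattern optional filename regex filter.
#' @return A [RunCollection-class] with runs sorted by filename.
#' @export
loadRunCollection <- function(dir,
                              format = c("auto", "admixture", "structure",
                                         "faststructure"),
                              labels = NULL, modelID = NA_character_,
                              pattern = NULL) {
    format <- match.arg(format)
    if (!dir.exists(dir)) stop(sprintf("directory '%s' does not exist", dir))
    files <- list.files(dir, full.names = TRUE, pattern = pattern)
    files <- files[!dir.exists(files)]
    files <- files[!grepl("\\.(json|txt|csv|log|yaml|yml)$", files,
                          ignore.case = TRUE) | format == "structure"]
    files <- sort(files)
    if (!length(files)) stop(sprintf("no run files found in '%s'", dir))
    parseOne <- function(f) {
        switch(format,
            admixture = readAdmixtureQ(f, modelID = modelID),
            faststructure = readFastStructureQ(f, modelID = modelID),
            structure = readStructureRun(f, modelID = modelID),
            auto = if (grepl("\\.(q|meanq)$", f, ignore.case = TRUE))
                       readAdmixtureQ(f, modelID = modelID)
                   else readStructureRun(f, modelID = modelID))
    }
    rl <- lapply(files, parseOne)
    ns <- vapply(rl, nIndividuals, integer(1))
    if (length(unique(ns)) != 1L) {
        tab <- split(basename(files), ns)
        msg <- paste(sprintf("N=%s: %s", names(tab),
                             vapply(tab, paste, character(1), collapse = ", ")),
                     collapse = "; ")
        stop("runs disagree on the number of individuals: ", msg)
    }
    if (is.character(labels)) labels <- readPopulationLabels(labels)
    runCollection(rl, labels = labels)
}

#' Write a membership matrix with relabeled clusters to a .Q file
#'
#' Applies a cluster relabeling (a permutation of 1..K: `relabeling[c]` is
#' the output column that input cluster c is written to) and writes the
#' matrix in the whitespace-delimited .Q dialect.  Values are written with
#' enough digits that a read/write round trip is exact to 1e-12.
#'
#' @param m a [MembershipMatrix-class].
#' @param relabeling integer permutation of 1..K (default identity).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAlignedQ <- function(m, relabeling = seq_len(nClusters(m)), path) {
    k <- nClusters(m)
    relabeling <- as.integer(relabeling)
    if (length(relabeling) != k || !identical(sort(relabeling), seq_len(k)))
        stop(sprintf("relabeling must be a permutation of 1..%d", k))
    out <- matrix(0, nIndividuals(m), k)
    out[, relabeling] <- memberships(m)
    writeQFile(out, path)
}
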