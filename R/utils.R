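# internal helpers

# evaluate expr under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

# one Dirichlet draw per row of alpha (rows with zero entries keep exact zeros)
rdirichletRows <- function(alpha) {
    stopifnot(is.matrix(alpha), all(alpha >= 0))
    g <- matrix(stats::rgamma(length(alpha), shape = as.vector(alpha), rate = 1),
                nrow = nrow(alpha))
    rs <- rowSums(g)
    bad <- rs <= 0
    if (any(bad)) {  # all-zero concentration row: fall back to its normalized alpha
        g[bad, ] <- alpha[bad, , drop = FALSE]
        rs[bad] <- rowSums(alpha[bad, , drop = FALSE])
    }
    g / rs
}

# fixed-format number used in every text artifact so artifacts are reproducible
fmtNum <- function(x) sprintf("%.15g", x)

writeQFile <- function(values, path) {
    lines <- apply(values, 1L, function(r) paste(fmtNum(r), collapse = " "))
    writeLines(lines, path)
    invisible(path)
}

stopIfMissingArtifact <- function(path, producedBy) {
    if (!file.exists(path)) {
        stop(sprintf("expected artifact '%s' not found; run step '%s' first",
                     path, producedBy), call. = FALSE)
    }
    invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
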