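#' Fixed categorical cluster palette
#'
#' A fixed, documented palette of 48 distinguishable colors keyed by global
#' cluster label, so the same cluster chain keeps its color in every figure
#' of a session and across sessions.  Order: a 12-color categorical core
#' (blue, orange, green, red, purple, brown, pink, gray, olive, cyan, navy,
#' gold), then 36 evenly spaced HCL hues at alternating luminance.
#'
#' @param n number of colors needed (<= 48 returns the leading n).
#' @return Character vector of n hex colors.
#' @export
clusterPalette <- function(n = 48L) {
    core <- c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
              "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf",
              "#000080", "#ffd700")
    extra <- grDevices::hcl(h = seq(15, 375, length.out = 37)[-37],
                            c = 80, l = rep(c(55, 75), length.out = 36))
    pal <- c(core, extra)
    if (n > length(pal))
        stop(sprintf("palette provides %d colors; %d requested", length(pal), n))
    pal[seq_len(n)]
}

#' Display order of individuals for bar plots
#'
#' Individuals are grouped by their population labels (in the labels' group
#' order); within each group they are sorted in descending order of
#' membership in that group's *dominant* cluster — the cluster with the
#' largest total membership over the group's individuals in the reference
#' matrix.  The sort is stable, so the rule is idempotent on its own output.
#'
#' @param ref reference [MembershipMatrix-class] (typically the major mode at
#'   the largest or smallest K).
#' @param labels a [PopulationLabels-class]; NULL keeps input order.
#' @param referenceMode mode ID recorded in the result.
#' @return A [DisplayOrder-class].
#' @export
reorderIndividuals <- function(ref, labels = NULL,
                               referenceMode = runID(ref)) {
    n <- nIndividuals(ref)
    if (is.null(labels))
        return(new("DisplayOrder", order = seq_len(n),
                   referenceMode = referenceMode))
    if (length(labels@labels) != n)
        stop(sprintf("have %d labels for %d individuals",
                     length(labels@labels), n))
    q <- memberships(ref)
    ord <- integer(0)
    for (grp in labels@groupOrder) {
        idx <- which(labels@labels == grp)
        dom <- which.max(colSums(q[idx, , drop = FALSE]))
        ord <- c(ord, idx[order(-q[idx, dom])])
    }
    new("DisplayOrder", order = ord, referenceMode = referenceMode)
}

# open a pdf or png device according to the file extension
openDevice <- function(path, width = 8, height = 5, dpi = 150) {
    ext <- tolower(tools::file_ext(path))
    if (ext == "png") {
        grDevices::png(path, width = width * dpi, height = height * dpi,
                       res = dpi)
    } else {
        grDevices::pdf(path, width = width, height = height)
    }
}

# draw one stacked bar plot into the rectangle [x0,x1] x [y0,y1] of the
# current plot; colors indexed by the cluster's global label
drawBars <- function(q, ord, labelColors, x0, x1, y0, y1, maxBars = 2000L) {
    n <- nrow(q)
    idx <- ord
    if (n > maxBars) {  # render-resolution subsampling only; data untouched
        warning(sprintf("rendering %d of %d bars (resolution subsampling)",
                        maxBars, n))
        idx <- ord[unique(round(seq(1L, n, length.out = maxBars)))]
    }
    nb <- length(idx)
    w <- (x1 - x0) / nb
    xl <- x0 + (seq_len(nb) - 1L) * w
    cum <- cbind(0, t(apply(q[idx, , drop = FALSE], 1L, cumsum)))
    for (k in seq_len(ncol(q))) {
        graphics::rect(xl, y0 + cum[, k] * (y1 - y0),
                       xl + w, y0 + cum[, k + 1L] * (y1 - y0),
                       col = labelColors[k], border = NA)
    }
    graphics::rect(x0, y0, x1, y1, border = "gray30", lwd = 0.4)
}

drawGroupMarks <- function(labels, ord, x0, x1, y0, names = TRUE) {
    if (is.null(labels)) return(invisible())
    labs <- labels@labels[ord]
    n <- length(labs)
    bounds <- which(labs[-1L] != labs[-n])
    xb <- x0 + bounds / n * (x1 - x0)
    graphics::segments(xb, y0, xb, y0 - 0.015, col = "gray30", lwd = 0.5)
    if (names) {
        starts <- c(0, bounds); ends <- c(bounds, n)
        mid <- x0 + (starts + ends) / 2 / n * (x1 - x0)
        graphics::text(mid, y0 - 0.02, labs[c(bounds, n)], cex = 0.4,
                       srt = 90, adj = c(1, 0.5), xpd = NA)
    }
    invisible()
}

#' Stacked bar plot of one membership matrix
#'
#' One stacked bar per individual in display order; segment heights are the
#' membership coefficients (so every bar has full height), colored by global
#' cluster label.  Group separators and names are drawn when labels exist.
#'
#' @param m a [MembershipMatrix-class].
#' @param order a [DisplayOrder-class] (default: input order).
#' @param clusterLabels integer vector mapping local cluster -> global label
#'   (default 1..K).
#' @param labels optional [PopulationLabels-class].
#' @param path output file (.pdf or .png).
#' @param width,height,dpi device geometry.
#' @return `path`, invisibly.
#' @export
plotModeBarplot <- function(m, order = NULL, clusterLabels = NULL,
                            labels = NULL, path, width = 8, height = 2.2,
                            dpi = 150) {
    ord <- if (is.null(order)) seq_len(nIndividuals(m)) else order@order
    gl <- if (is.null(clusterLabels)) seq_len(nClusters(m)) else clusterLabels
    pal <- clusterPalette(max(gl))
    openDevice(path, width, height, dpi)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(2.2, 1, 1.4, 1))
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, 1), ylim = c(-0.05, 1))
    drawBars(memberships(m), ord, pal[gl], 0, 1, 0, 1)
    drawGroupMarks(labels, ord, 0, 1, 0)
    graphics::title(main = runID(m), cex.main = 0.9)
    invisible(path)
}

#' Multipartite bar-plot graph of aligned modes
#'
#' Modes are arranged in rows by K (ascending top to bottom), each drawn as a
#' stacked bar plot annotated with its size "(s)" at the upper left and its
#' within-mode similarity at the upper right.  Modes at adjacent K values are
#' connected by edges labeled with the alignment cost; edge gray level maps
#' similarity linearly from black (similarity 1) to light gray (the minimum
#' similarity in the graph, floored at 0.8 luminance).
#'
#' @param g a [ModeAlignmentGraph-class].
#' @param order optional [DisplayOrder-class].
#' @param labels optional [PopulationLabels-class].
#' @param path output file (.pdf or .png).
#' @param width,height,dpi device geometry (height defaults to 1.6 per K row).
#' @return `path`, invisibly.
#' @export
plotMultipartite <- function(g, order = NULL, labels = NULL, path,
                             width = 10, height = NULL, dpi = 150) {
    kv <- g@kValues
    if (is.null(height)) height <- max(3, 1.6 * length(kv))
    lay <- multipartiteLayout(g)
    sims <- vapply(g@edges, function(e) e$alignment@similarity, numeric(1))
    grayOf <- edgeGrayScale(sims)
    openDevice(path, width, height, dpi)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(1, 2.5, 1, 1))
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1))
    for (e in g@edges) {
        a <- lay[[e$lower]]; b <- lay[[e$upper]]
        x0 <- mean(c(a$x0, a$x1)); x1 <- mean(c(b$x0, b$x1))
        graphics::segments(x0, a$y0, x1, b$y1,
                           col = grayOf(e$alignment@similarity),
                           lwd = if (e$isAnchor) 1.6 else 0.9,
                           lty = if (e$isAnchor) 1 else 2)
        graphics::text((x0 + x1) / 2, (a$y0 + b$y1) / 2,
                       formatC(e$alignment@cost, format = "g", digits = 3),
                       cex = 0.55, col = "gray20")
    }
    firstInRow <- vapply(split(names(lay),
                               vapply(g@modes[names(lay)], modeK, integer(1))),
                         `[`, character(1), 1L)
    for (id in names(lay)) {
        cell <- lay[[id]]
        mode <- g@modes[[id]]
        q <- memberships(representative(mode))
        ord <- if (is.null(order)) seq_len(nrow(q)) else order@order
        pal <- clusterPalette(max(unlist(g@clusterLabels)))
        drawBars(q, ord, pal[g@clusterLabels[[id]]],
                 cell$x0, cell$x1, cell$y0, cell$y1)
        if (!is.null(labels) && id %in% firstInRow)
            drawGroupMarks(labels, ord, cell$x0, cell$x1, cell$y0,
                           names = modeK(mode) == max(kv))
        graphics::text(cell$x0, cell$y1 + 0.012,
                       sprintf("%s (%d)", id, modeSize(mode)),
                       cex = 0.6, adj = c(0, 0))
        graphics::text(cell$x1, cell$y1 + 0.012,
                       sprintf("sim=%.3f", withinSimilarity(mode)),
                       cex = 0.6, adj = c(1, 0))
    }
    graphics::mtext(sprintf("K=%d", kv), side = 2,
                    at = vapply(as.character(kv), function(k) {
                        ids <- names(g@modes)[vapply(g@modes, modeK,
                                                     integer(1)) == as.integer(k)]
                        mean(c(lay[[ids[1L]]]$y0, lay[[ids[1L]]]$y1))
                    }, numeric(1)), cex = 0.7, las = 1, line = 0.5)
    invisible(path)
}

# rows by K ascending top -> bottom; modes side by side within a row
multipartiteLayout <- function(g, barH = 0.62) {
    kv <- g@kValues
    nr <- length(kv)
    rowH <- 1 / nr
    lay <- list()
    for (i in seq_along(kv)) {
        ids <- names(g@modes)[vapply(g@modes, modeK, integer(1)) == kv[i]]
        nm <- length(ids)
        y1 <- 1 - (i - 1) * rowH - 0.12 * rowH
        y0 <- y1 - barH * rowH
        cellW <- 1 / nm
        for (j in seq_along(ids)) {
            x0 <- (j - 1) * cellW + 0.06 * cellW
            x1 <- j * cellW - 0.06 * cellW
            lay[[ids[j]]] <- list(x0 = x0, x1 = x1, y0 = y0, y1 = y1)
        }
    }
    lay
}

# linear similarity -> gray mapping: 1 -> black, min similarity -> gray(0.8)
edgeGrayScale <- function(sims) {
    lo <- if (length(sims)) min(sims) else 0
    function(s) {
        if (lo >= 1) return(grDevices::gray(0))
        lev <- 0.8 * (1 - s) / (1 - lo)
        grDevices::gray(max(0, min(0.8, lev)))
    }
}

#' Alignment pattern graph
#'
#' Modes are laid out as in [plotMultipartite()] but drawn as K nodes (one
#' per cluster, colored by global label, newly emerged labels appended to the
#' right).  Edges trace the cross-K cluster matchings: connections to newly
#' emerged clusters are drawn prominently while direct-match connections are
#' dimmed (reduced opacity); anchor-pair edges are solid, all others dashed.
#'
#' @param edges data.frame from [patternEdges()] (computed from `g` when
#'   omitted).
#' @param g a [ModeAlignmentGraph-class].
#' @param path output file (.pdf or .png).
#' @param width,height,dpi device geometry.
#' @return `path`, invisibly.
#' @export
plotAlignmentPattern <- function(g, edges = patternEdges(g), path,
                                 width = 8, height = NULL, dpi = 150) {
    kv <- g@kValues
    if (is.null(height)) height <- max(3, 1.2 * length(kv))
    lay <- multipartiteLayout(g, barH = 0.5)
    pal <- clusterPalette(max(unlist(g@clusterLabels)))
    # node positions: clusters ordered by global label, left to right
    nodePos <- list()
    for (id in names(lay)) {
        cell <- lay[[id]]
        gl <- g@clusterLabels[[id]]
        xs <- seq(cell$x0 + 0.05 * (cell$x1 - cell$x0),
                  cell$x1 - 0.05 * (cell$x1 - cell$x0),
                  length.out = length(gl))
        o <- order(gl)
        y <- mean(c(cell$y0, cell$y1))
        for (j in seq_along(gl)) {
            c_local <- o[j]
            nodePos[[paste(id, gl[c_local], sep = "#")]] <-
                list(x = xs[j], y = y, col = pal[gl[c_local]])
        }
    }
    openDevice(path, width, height, dpi)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(0.5, 2.5, 0.5, 0.5))
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1))
    if (nrow(edges)) {
        for (i in seq_len(nrow(edges))) {
            e <- edges[i, ]
            a <- nodePos[[paste(e$parentMode, e$parentLabel, sep = "#")]]
            b <- nodePos[[paste(e$childMode, e$childLabel, sep = "#")]]
            prominent <- isTRUE(e$isNewClusterEdge)
            graphics::segments(a$x, a$y, b$x, b$y,
                col = grDevices::adjustcolor("gray10",
                                             alpha.f = if (prominent) 1 else 0.2),
                lwd = if (prominent) 1.8 else 0.7,
                lty = if (isTRUE(e$isAnchor)) 1 else 2)
        }
    }
    for (nm in names(nodePos)) {
        p <- nodePos[[nm]]
        graphics::points(p$x, p$y, pch = 21, bg = p$col, col = "gray20",
                         cex = 1.8)
    }
    for (id in names(lay)) {
        cell <- lay[[id]]
        graphics::text(cell$x0, mean(c(cell$y0, cell$y1)), id, cex = 0.6,
                       adj = c(1.1, 0.5))
    }
    graphics::mtext(sprintf("K=%d", kv), side = 2,
                    at = seq(1 - 0.5 / length(kv), 0.5 / length(kv),
                             length.out = length(kv)),
                    cex = 0.7, las = 1, line = 0.5)
    invisible(path)
}
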