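## Relative-abundance scaling across histotypes and per-pathway bubble
## summaries: the highest histotype value of a protein is set to 100, the
## others become relative percentages; >= 50 counts as up-represented.

#' Relative spectral-count scaling and up/down classification
#'
#' For each protein, the highest histotype-mean value is set to 100 and the
#' other histotypes are expressed relative to it. A protein is
#' up-represented in a histotype iff its relative value is equal to or
#' higher than 50 (inclusive), otherwise down-represented. Ties at the
#' maximum all receive 100.
#'
#' @param x histotype-level [SpcExperiment-class] (typically HR proteins);
#'   every protein must have a positive maximum.
#' @param cutoff up/down boundary on the relative scale (default 50,
#'   inclusive).
#' @return data.frame with columns \code{accession}, \code{histotype},
#'   \code{relative} in \eqn{[0, 100]} and \code{class} (\code{up}/\code{down}).
#' @export
relativeScale <- function(x, cutoff = 50) {
    stopifnot(is(x, "SpcExperiment"), spcLevel(x) == "histotype")
    m <- spc(x)
    mx <- apply(m, 1L, max)
    if (any(mx == 0))
        stop("validation error: protein(s) with all-zero values: ",
             paste(utils::head(rownames(m)[mx == 0], 3L), collapse = ", "))
    rel <- 100 * m / mx
    data.frame(
        accession = rep(rownames(m), times = ncol(m)),
        histotype = rep(colnames(m), each = nrow(m)),
        relative = as.vector(rel),
        class = factor(ifelse(as.vector(rel) >= cutoff, "up", "down"),
                       levels = c("up", "down")),
        row.names = NULL)
}

#' Per-pathway bubble summary of up/down-represented proteins
#'
#' Counts, per pathway and histotype, the annotated proteins classified up
#' and down by [relativeScale()]. A protein may contribute to several
#' pathways; proteins not annotated to a pathway are ignored for it. The
#' total per pathway is identical across histotypes.
#'
#' @param rep representation table from [relativeScale()].
#' @param pathways pathway annotation, a named list of member accession
#'   vectors ([readGMT()]).
#' @param selected pathway ids to summarize (default: all).
#' @return data.frame with columns \code{pathway}, \code{histotype},
#'   \code{n_total}, \code{n_up}, \code{n_down}.
#' @export
bubbleSummary <- function(rep, pathways, selected = names(pathways)) {
    unknown <- setdiff(selected, names(pathways))
    if (length(unknown))
        stop("validation error: unknown pathway id(s): ",
             paste(unknown, collapse = ", "))
    hts <- unique(rep$histotype)
    accs <- unique(rep$accession)
    out <- do.call(rbind, lapply(selected, function(pw) {
        members <- intersect(pathways[[pw]], accs)
        sub <- rep[rep$accession %in% members, , drop = FALSE]
        do.call(rbind, lapply(hts, function(h) {
            cls <- sub$class[sub$histotype == h]
            data.frame(pathway = pw, histotype = h,
                       n_total = length(members),
                       n_up = sum(cls == "up"),
                       n_down = sum(cls == "down"),
                       row.names = NULL)
        }))
    }))
    rownames(out) <- NULL
    out
}

#' Render a bubble chart of pathway representation
#'
#' One circle per (pathway, histotype): circle area is proportional to the
#' number of annotated proteins, the orange sector fraction to the
#' up-represented share and the light-blue sector to the down-represented
#' share. Pathways are rows, histotypes columns; layout is deterministic.
#' Empty pathways (n_total = 0) are drawn as a dot placeholder.
#'
#' @param summary bubble summary from [bubbleSummary()].
#' @param path output file; device chosen by extension (\code{.pdf},
#'   \code{.png} or \code{.svg}).
#' @param maxRadius radius (in user units) of the largest bubble.
#' @return the output path, invisibly.
#' @export
renderBubbleChart <- function(summary, path, maxRadius = 0.42) {
    stopifnot(nrow(summary) > 0)
    pws <- unique(summary$pathway)
    hts <- unique(summary$histotype)
    ext <- tolower(sub(".*\\.", "", path))
    h <- max(3, 0.45 * length(pws) + 1)
    w <- max(4, 1.2 * length(hts) + 3)
    switch(ext,
        pdf = grDevices::pdf(path, width = w, height = h),
        png = grDevices::png(path, width = 100 * w, height = 100 * h, res = 100),
        svg = grDevices::svg(path, width = w, height = h),
        stop("unsupported extension '", ext, "' (use pdf, png or svg)"))
    on.exit(grDevices::dev.off())
    op <- graphics::par(mar = c(1, 10, 3, 1))
    on.exit(graphics::par(op), add = TRUE, after = FALSE)
    graphics::plot(NA, xlim = c(0.5, length(hts) + 0.5),
                   ylim = c(length(pws) + 0.5, 0.5),
                   axes = FALSE, xlab = "", ylab = "", asp = 1)
    graphics::axis(3, at = seq_along(hts), labels = hts, tick = FALSE)
    graphics::axis(2, at = seq_along(pws), labels = pws, tick = FALSE,
                   las = 2, cex.axis = 0.8)
    nmax <- max(summary$n_total)
    for (i in seq_len(nrow(summary))) {
        xi <- match(summary$histotype[i], hts)
        yi <- match(summary$pathway[i], pws)
        n <- summary$n_total[i]
        if (n == 0 || nmax == 0) {
            graphics::points(xi, yi, pch = 3, col = "grey70", cex = 0.5)
            next
        }
        r <- maxRadius * sqrt(n / nmax)  # area proportional to n_total
        .sector(xi, yi, r, frac = summary$n_up[i] / n, col = "orange")
        .sector(xi, yi, r, frac0 = summary$n_up[i] / n, frac = 1,
                col = "lightblue")
    }
    invisible(path)
}

## filled circular sector from frac0 to frac (fractions of a full turn,
## clockwise from 12 o'clock)
.sector <- function(x, y, r, frac, frac0 = 0, col) {
    if (frac <= frac0) return(invisible())
    th <- pi / 2 - 2 * pi * seq(frac0, frac, length.out = 64)
    xs <- c(if (frac - frac0 < 1) x, x + r * cos(th))
    ys <- c(if (frac - frac0 < 1) y, y + r * sin(th))
    graphics::polygon(xs, ys, col = col, border = "grey30")
}
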