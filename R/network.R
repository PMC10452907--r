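## PPI edge filtering and network node annotation. Edges come from a local
## edge list with per-channel confidence scores ("databases",
## "experiments"); an interacting pair is retained when either channel
## clears its threshold, which keeps the analysis hermetic (no live
## database queries).

#' Filter a PPI edge list by per-channel score thresholds
#'
#' Duplicate pairs (in either orientation) are merged first, keeping the
#' per-channel maximum score. A pair is retained iff its
#' \code{databases}-channel score is \eqn{\ge} \code{dbThr} \emph{or} its
#' \code{experiments}-channel score is \eqn{\ge} \code{expThr} (both
#' inclusive). Filtering is idempotent, and raising either threshold never
#' adds edges.
#'
#' @param edges data.frame with columns \code{protein_a}, \code{protein_b},
#'   \code{channel}, \code{score} ([readPpiEdges()]).
#' @param dbThr,expThr inclusive thresholds in \eqn{[0, 1]} for the
#'   \code{databases} and \code{experiments} channels (defaults 0.3, 0.15).
#' @return filtered edge list in the same long format, pairs in canonical
#'   orientation (\code{protein_a < protein_b}).
#' @export
filterPpiEdges <- function(edges, dbThr = 0.3, expThr = 0.15) {
    stopifnot(dbThr >= 0, dbThr <= 1, expThr >= 0, expThr <= 1)
    if (!nrow(edges)) return(edges)
    a <- pmin(edges$protein_a, edges$protein_b)
    b <- pmax(edges$protein_a, edges$protein_b)
    key <- paste(a, b, edges$channel, sep = "\r")
    agg <- stats::aggregate(edges$score, by = list(key = key), FUN = max)
    parts <- do.call(rbind, strsplit(agg$key, "\r", fixed = TRUE))
    merged <- data.frame(protein_a = parts[, 1L], protein_b = parts[, 2L],
                         channel = parts[, 3L], score = agg$x,
                         stringsAsFactors = FALSE)
    pair <- paste(merged$protein_a, merged$protein_b, sep = "\r")
    db <- merged$channel == "databases" & merged$score >= dbThr
    ex <- merged$channel == "experiments" & merged$score >= expThr
    keep_pairs <- unique(pair[db | ex])
    out <- merged[pair %in% keep_pairs, , drop = FALSE]
    out <- out[order(out$protein_a, out$protein_b, out$channel), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Annotate an HR protein network
#'
#' Builds the node attribute table used to render per-histotype network
#' views: every HR protein is a node (isolated proteins keep degree 0), with
#' a DEP flag (called in any comparison), its specific-HR histotype if any,
#' and per-histotype relative abundances in \eqn{[0, 100]} as the node color
#' scale. Edges whose endpoints fall outside the node set are dropped with a
#' warning.
#'
#' @param nodes HR accession set.
#' @param deps DEP table from [callDEPs()] (or NULL).
#' @param specific named list of histotype-specific HR sets (or NULL).
#' @param rep representation table from [relativeScale()].
#' @param edges filtered edge list from [filterPpiEdges()] (or NULL).
#' @return list with \code{nodes} (data.frame), \code{edges} (one row per
#'   pair with per-channel scores spread to columns) and \code{graph}
#'   (igraph object).
#' @export
annotateNetwork <- function(nodes, deps = NULL, specific = NULL, rep, edges = NULL) {
    nodes <- sort(unique(nodes))
    nd <- data.frame(accession = nodes, is_dep = FALSE,
                     specific_histotype = NA_character_,
                     stringsAsFactors = FALSE)
    if (!is.null(deps))
        nd$is_dep <- nd$accession %in% depAccessions(deps)
    if (!is.null(specific))
        for (h in names(specific))
            nd$specific_histotype[nd$accession %in% specific[[h]]] <- h
    for (h in unique(rep$histotype)) {
        v <- rep$relative[rep$histotype == h]
        names(v) <- rep$accession[rep$histotype == h]
        nd[[paste0("relative_", h)]] <- unname(v[nd$accession])
    }
    if (is.null(edges) || !nrow(edges)) {
        ed <- data.frame(protein_a = character(), protein_b = character(),
                         databases = numeric(), experiments = numeric())
    } else {
        ok <- edges$protein_a %in% nodes & edges$protein_b %in% nodes
        if (any(!ok))
            warning("dropping ", length(unique(paste(edges$protein_a,
                    edges$protein_b)[!ok])),
                    " edge pair(s) with endpoint(s) outside the node set")
        edges <- edges[ok, , drop = FALSE]
        pair <- unique(edges[, c("protein_a", "protein_b")])
        ed <- pair
        for (ch in c("databases", "experiments")) {
            sc <- edges[edges$channel == ch, , drop = FALSE]
            idx <- match(paste(pair$protein_a, pair$protein_b),
                         paste(sc$protein_a, sc$protein_b))
            ed[[ch]] <- sc$score[idx]
        }
        rownames(ed) <- NULL
    }
    g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nd)
    list(nodes = nd, edges = ed, graph = g)
}
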