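## Overrepresentation analysis: upper-tail hypergeometric test of a query
## set against pathway annotations within an explicit universe, with
## Benjamini-Hochberg adjustment across the tested pathways.

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate adjustment with enforced
#' monotonicity, capped at 1; the output order matches the input order.
#'
#' @param p p-values in \eqn{(0, 1]}.
#' @return adjusted values, same length and order.
#' @export
#' @examples
#' bhFDR(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
bhFDR <- function(p) {
    if (!length(p)) stop("validation error: empty p-value vector")
    if (anyNA(p) || any(p <= 0 | p > 1))
        stop("validation error: p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Hypergeometric overrepresentation analysis
#'
#' For each pathway, tests whether the query set overlaps the pathway more
#' than expected under hypergeometric sampling from the universe:
#' \eqn{p = P(X \ge k)} with \eqn{X \sim Hypergeom(N, K, n)}, where \eqn{N}
#' is the universe size, \eqn{K} the pathway size within the universe,
#' \eqn{n} the query size and \eqn{k} the observed overlap. Pathway members
#' outside the universe are ignored. P-values are BH-adjusted across all
#' tested pathways; a pathway is flagged significant when both the raw p and
#' the FDR fall below their thresholds.
#'
#' The universe is an explicit argument by design: results depend on it, and
#' sensible choices differ (all identified proteins, the HR set, or a custom
#' background).
#'
#' @param query accession set of interest; must be a subset of
#'   \code{universe}.
#' @param pathways named list of member accession vectors ([readGMT()]).
#' @param universe background accession set.
#' @param alpha threshold on the raw p-value (default 0.05).
#' @param fdrThr threshold on the BH-adjusted value (default \code{alpha};
#'   use 0.01 for the stricter network-module variant).
#' @return data.frame sorted by p-value with columns \code{pathway},
#'   \code{k}, \code{n}, \code{K}, \code{N}, \code{p_value}, \code{fdr},
#'   \code{significant}.
#' @export
hypergeomORA <- function(query, pathways, universe, alpha = 0.05,
                         fdrThr = alpha) {
    query <- unique(query)
    universe <- unique(universe)
    if (!all(query %in% universe))
        stop("validation error: query contains accession(s) outside the universe")
    if (!length(pathways)) stop("validation error: no pathways to test")
    N <- length(universe)
    n <- length(query)
    res <- do.call(rbind, lapply(names(pathways), function(pw) {
        members <- intersect(unique(pathways[[pw]]), universe)
        K <- length(members)
        k <- length(intersect(members, query))
        p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(pathway = pw, k = k, n = n, K = K, N = N,
                   p_value = p, row.names = NULL)
    }))
    res$fdr <- bhFDR(res$p_value)
    res$significant <- res$p_value < alpha & res$fdr < fdrThr
    res <- res[order(res$p_value, res$pathway), , drop = FALSE]
    rownames(res) <- NULL
    res
}
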