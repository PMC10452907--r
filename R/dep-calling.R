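## DAve/DCI differential calling on highly reproducible proteins. Both
## indexes are deliberately kept as one-line pure functions: an alternative
## scaling convention is a one-line change, and the threshold boundary
## DAve(15, 10) = 0.4, DCI(15, 10) = 62.5 is pinned in the tests.

#' Differential average (DAve)
#'
#' \deqn{DAve = \frac{a - b}{(a + b)/2} = \frac{2(a - b)}{a + b}}
#' the difference between two mean spectral counts relative to their average,
#' bounded in \eqn{[-2, 2]}. Defined as 0 when \eqn{a + b = 0}.
#'
#' @param a,b non-negative mean spectral counts (vectorized).
#' @return numeric in \eqn{[-2, 2]}.
#' @export
#' @examples
#' computeDAve(15, 10)  # 0.4, the usual calling threshold
computeDAve <- function(a, b) {
    if (any(a < 0) || any(b < 0))
        stop("validation error: mean counts must be >= 0")
    s <- a + b
    ifelse(s == 0, 0, 2 * (a - b) / s)
}

#' Differential confidence index (DCI)
#'
#' \deqn{DCI = \frac{(a + b)(a - b)}{2}}
#' an abundance-weighted difference: the same relative change scores higher
#' at higher abundance (\eqn{DCI(ka, kb) = k^2 DCI(a, b)}), so low-count
#' proteins cannot be called on ratio alone.
#'
#' @inheritParams computeDAve
#' @return numeric, unbounded.
#' @export
#' @examples
#' computeDCI(15, 10)   # 62.5
#' computeDCI(1.2, 0.8) # 0.4 — too low-abundant to clear a DCI cutoff of 5
computeDCI <- function(a, b) {
    if (any(a < 0) || any(b < 0))
        stop("validation error: mean counts must be >= 0")
    (a + b) * (a - b) / 2
}

#' Call differentially expressed proteins with DAve/DCI thresholds
#'
#' For each protein and each ordered histotype comparison \code{(first,
#' second)}, computes DAve and DCI on the histotype-mean spectral counts and
#' calls, relative to the first condition:
#' \code{up} if \eqn{DAve \ge +daveThr} and \eqn{DCI \ge +dciThr},
#' \code{down} if \eqn{DAve \le -daveThr} and \eqn{DCI \le -dciThr},
#' \code{none} otherwise. Thresholds are inclusive. A protein is a DEP iff
#' it is called in at least one comparison.
#'
#' @param x histotype-level [SpcExperiment-class], typically restricted to
#'   HR proteins beforehand.
#' @param comparisons list of ordered histotype pairs; default all pairs in
#'   canonical column order (for SM, CS, CG: SM vs CS, SM vs CG, CS vs CG).
#' @param daveThr,dciThr positive calling thresholds (defaults 0.4 and 5).
#' @return data.frame with one row per (protein, comparison): columns
#'   \code{accession}, \code{comparison}, \code{a}, \code{b}, \code{dave},
#'   \code{dci}, \code{call}.
#' @export
callDEPs <- function(x, comparisons = NULL, daveThr = 0.4, dciThr = 5) {
    stopifnot(is(x, "SpcExperiment"), spcLevel(x) == "histotype",
              daveThr > 0, dciThr > 0)
    hts <- colnames(x)
    if (is.null(comparisons))
        comparisons <- utils::combn(hts, 2L, simplify = FALSE)
    for (cmp in comparisons) {
        if (length(cmp) != 2L || !all(cmp %in% hts))
            stop("validation error: unknown histotype in comparison: ",
                 paste(cmp, collapse = " vs "))
    }
    m <- spc(x)
    out <- do.call(rbind, lapply(comparisons, function(cmp) {
        a <- m[, cmp[1L]]
        b <- m[, cmp[2L]]
        dave <- computeDAve(a, b)
        dci <- computeDCI(a, b)
        call <- ifelse(dave >= daveThr & dci >= dciThr, "up",
                ifelse(dave <= -daveThr & dci <= -dciThr, "down", "none"))
        data.frame(accession = rownames(m),
                   comparison = paste(cmp[1L], "vs", cmp[2L]),
                   a = a, b = b, dave = dave, dci = dci,
                   call = factor(call, levels = c("up", "down", "none")),
                   row.names = NULL)
    }))
    attr(out, "thresholds") <- c(dave = daveThr, dci = dciThr)
    out
}

#' @describeIn callDEPs accessions called in at least one comparison.
#' @param deps a DEP table from \code{callDEPs()}.
#' @export
depAccessions <- function(deps) {
    sort(unique(deps$accession[deps$call != "none"]))
}
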