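## Stability and homogeneity statistics: Levene + one-way ANOVA across a
## histotype's sequential samples (composition stability), and Pearson
## chi-square homogeneity of source-class proportions across histotypes.

#' Stability of composition across a histotype's sequential samples
#'
#' Treats each sample (master list) of a histotype as a group and each
#' protein's normalized spectral count as an observation, over the union of
#' proteins identified in any of the histotype's samples (absence counted
#' as 0). Runs Levene's test for equality of variances (mean-centered by
#' default; \code{center = "median"} gives the Brown-Forsythe variant)
#' followed by a one-way fixed-effects ANOVA. Large p-values indicate that
#' the fluid's composition did not shift between timepoints.
#'
#' @param masters sample-level [SpcExperiment-class].
#' @param histotype histotypes to test (default: all with \eqn{\ge 2}
#'   samples); each tested histotype needs at least two samples.
#' @param center centering for Levene's test, \code{"mean"} or
#'   \code{"median"}.
#' @return data.frame with one row per histotype: \code{histotype},
#'   \code{levene_stat}, \code{levene_p}, \code{f_ratio}, \code{anova_p},
#'   \code{groups}, \code{n_per_group}.
#' @export
stabilityAnova <- function(masters, histotype = NULL,
                           center = c("mean", "median")) {
    stopifnot(is(masters, "SpcExperiment"), spcLevel(masters) == "sample")
    center <- match.arg(center)
    cd <- as.data.frame(colData(masters))
    if (is.null(histotype)) {
        counts <- table(cd$histotype)
        histotype <- histotypes(masters)[histotypes(masters) %in%
                                             names(counts)[counts >= 2]]
    }
    out <- do.call(rbind, lapply(histotype, function(h) {
        cols <- cd$sample_id[cd$histotype == h]
        if (length(cols) < 2L)
            stop("validation error: histotype '", h,
                 "' has fewer than 2 samples")
        m <- spc(masters)[, cols, drop = FALSE]
        m <- m[rowSums(m) > 0, , drop = FALSE]
        long <- data.frame(value = as.vector(m),
                           sample = factor(rep(cols, each = nrow(m))))
        lev <- car::leveneTest(value ~ sample, data = long,
                               center = if (center == "mean") mean else median)
        fit <- stats::anova(stats::aov(value ~ sample, data = long))
        f <- fit[["F value"]][1L]
        p <- fit[["Pr(>F)"]][1L]
        data.frame(histotype = h,
                   levene_stat = lev[["F value"]][1L],
                   levene_p = lev[["Pr(>F)"]][1L],
                   f_ratio = f, anova_p = p,
                   groups = length(cols), n_per_group = nrow(m),
                   row.names = NULL)
    }))
    rownames(out) <- NULL
    out
}

#' Pearson chi-square test of homogeneity
#'
#' Tests whether column-wise proportions of a class x group count table are
#' homogeneous, without continuity correction;
#' \eqn{df = (r - 1)(c - 1)} (6 for a 4-class x 3-histotype table).
#'
#' @param observed count matrix (classes x groups), all row and column sums
#'   positive and all expected counts positive.
#' @return list with \code{chi2}, \code{df}, \code{p}, \code{observed},
#'   \code{expected}.
#' @export
#' @examples
#' chiSquareHomogeneity(rbind(c(10, 10), c(10, 10)))$chi2  # 0
chiSquareHomogeneity <- function(observed) {
    observed <- as.matrix(observed)
    if (any(rowSums(observed) == 0) || any(colSums(observed) == 0))
        stop("validation error: zero row or column in the observed table")
    res <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
    if (any(res$expected <= 0))
        stop("validation error: non-positive expected count")
    list(chi2 = unname(res$statistic), df = unname(res$parameter),
         p = unname(res$p.value), observed = observed,
         expected = res$expected)
}
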