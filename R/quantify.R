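## Total-signal normalization and hierarchical averaging of spectral counts:
## runs -> per-sample master lists -> per-histotype protein lists.

#' Total-signal normalization of run-level spectral counts
#'
#' Rescales each run so that all runs share a common total signal: counts in
#' run \eqn{j} are multiplied by \eqn{T / t_j}, where \eqn{t_j} is the run's
#' raw total and \eqn{T} the mean of all run totals. The mean-total reference
#' keeps values on the familiar spectral-count scale; zeros stay zero and
#' every normalized run sums to \eqn{T}.
#'
#' @param x run-level [SpcExperiment-class] with raw counts.
#' @return run-level \code{SpcExperiment} with normalized counts;
#'   \code{metadata()} records \code{normalized = TRUE}, the
#'   \code{reference_total} and the per-run \code{scaling_factors}.
#' @export
normalizeTotalSignal <- function(x) {
    stopifnot(is(x, "SpcExperiment"))
    if (spcLevel(x) != "run")
        stop("validation error: normalization applies to run-level data")
    m <- spc(x)
    totals <- colSums(m)
    if (any(totals == 0))
        stop("validation error: run(s) with zero total signal: ",
             paste(colnames(m)[totals == 0], collapse = ", "))
    ref <- mean(totals)
    factors <- ref / totals
    out <- SpcExperiment(sweep(m, 2L, factors, `*`),
                         colData = colData(x), level = "run",
                         rowData = rowData(x))
    metadata(out)$normalized <- TRUE
    metadata(out)$reference_total <- ref
    metadata(out)$scaling_factors <- factors
    out
}

#' Build per-sample master protein lists
#'
#' Averages each sample's normalized counts over its technical replicates. A
#' protein absent from a replicate contributes 0 to the mean (so a protein
#' seen in one of two replicates at 6 averages to 3); proteins absent from
#' every column are dropped. A protein is "present" in a sample's master
#' list iff its averaged value is strictly positive, i.e. it was identified
#' in at least one replicate.
#'
#' @param x normalized run-level [SpcExperiment-class].
#' @return sample-level \code{SpcExperiment}; colData has one row per sample
#'   (\code{sample_id}, \code{histotype}, \code{timepoint},
#'   \code{n_replicates}).
#' @export
buildMasterLists <- function(x) {
    stopifnot(is(x, "SpcExperiment"))
    if (spcLevel(x) != "run")
        stop("validation error: master lists are built from run-level data")
    cd <- as.data.frame(colData(x))
    samples <- unique(cd$sample_id)
    m <- spc(x)
    avg <- vapply(samples, function(s) {
        rowMeans(m[, cd$sample_id == s, drop = FALSE])
    }, numeric(nrow(m)))
    colnames(avg) <- samples
    keep <- rowSums(avg) > 0
    info <- cd[!duplicated(cd$sample_id),
               c("sample_id", "histotype", "timepoint")]
    info$n_replicates <- as.integer(table(cd$sample_id)[info$sample_id])
    rownames(info) <- info$sample_id
    out <- SpcExperiment(avg[keep, , drop = FALSE], colData = info,
                         level = "sample",
                         rowData = rowData(x)[keep, , drop = FALSE])
    metadata(out) <- metadata(x)
    out
}

#' @describeIn buildMasterLists extract one sample's master list as a named
#'   vector of strictly positive averaged counts.
#' @param sample sample identifier.
#' @export
masterList <- function(x, sample) {
    stopifnot(is(x, "SpcExperiment"), spcLevel(x) == "sample")
    if (!sample %in% colnames(x))
        stop("validation error: unknown sample '", sample, "'")
    v <- spc(x)[, sample]
    v[v > 0]
}

#' Average sample master lists into per-histotype protein lists
#'
#' Per histotype, a protein's value is the arithmetic mean of its master-list
#' values over that histotype's samples, counting absence in a sample as 0.
#'
#' @param x sample-level [SpcExperiment-class] from [buildMasterLists()].
#' @return histotype-level \code{SpcExperiment}.
#' @export
averageHistotype <- function(x) {
    stopifnot(is(x, "SpcExperiment"))
    if (spcLevel(x) != "sample")
        stop("validation error: histotype averaging applies to sample-level data")
    if (ncol(x) == 0L) stop("validation error: no samples")
    cd <- as.data.frame(colData(x))
    hts <- histotypes(x)
    m <- spc(x)
    avg <- vapply(hts, function(h) {
        rowMeans(m[, cd$histotype == h, drop = FALSE])
    }, numeric(nrow(m)))
    colnames(avg) <- hts
    keep <- rowSums(avg) > 0
    info <- data.frame(histotype = hts,
                       n_samples = as.integer(table(cd$histotype)[hts]),
                       row.names = hts)
    out <- SpcExperiment(avg[keep, , drop = FALSE], colData = info,
                         level = "histotype",
                         rowData = rowData(x)[keep, , drop = FALSE])
    metadata(out) <- metadata(x)
    out
}
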