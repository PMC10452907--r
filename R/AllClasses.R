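#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

#' Spectral-count experiment container
#'
#' An \code{SpcExperiment} holds a proteins x columns matrix of spectral
#' counts (assay \code{"spc"}) at one of three aggregation levels:
#' \describe{
#'   \item{\code{"run"}}{one column per LC-MS/MS run; raw or total-signal
#'     normalized counts. \code{colData} carries the study manifest
#'     (\code{run_id}, \code{sample_id}, \code{histotype}, \code{timepoint},
#'     \code{replicate}).}
#'   \item{\code{"sample"}}{one column per biological sample (a "master
#'     protein list"): normalized counts averaged over that sample's
#'     technical replicates, absence counted as zero.}
#'   \item{\code{"histotype"}}{one column per histotype: sample master lists
#'     averaged within histotype.}
#' }
#' Absence of a protein from a column is encoded as 0; presence means a
#' strictly positive value. Levels only move forward
#' (run -> sample -> histotype) via [buildMasterLists()] and
#' [averageHistotype()].
#'
#' @slot spcLevel character scalar, one of \code{"run"}, \code{"sample"},
#'   \code{"histotype"}.
#' @export
setClass("SpcExperiment",
    contains = "SummarizedExperiment",
    slots = c(spcLevel = "character")
)

setValidity("SpcExperiment", function(object) {
    msg <- character()
    if (length(object@spcLevel) != 1L ||
        !object@spcLevel %in% c("run", "sample", "histotype"))
        msg <- c(msg, "spcLevel must be one of 'run', 'sample', 'histotype'")
    if (!"spc" %in% names(assays(object)))
        msg <- c(msg, "an assay named 'spc' is required")
    else {
        m <- assay(object, "spc")
        if (anyNA(m)) msg <- c(msg, "spc values must not be NA")
        else if (any(m < 0)) msg <- c(msg, "spc values must be >= 0")
        if (is.null(rownames(object)))
            msg <- c(msg, "rownames (protein accessions) are required")
        else if (anyDuplicated(rownames(object)))
            msg <- c(msg, "protein accessions must be unique")
    }
    if (length(msg)) msg else TRUE
})

#' Presence/absence partition of a multi-histotype study
#'
#' Produced by [vennPartition()]. Captures, for a sample-level
#' \code{SpcExperiment}, which proteins each histotype identified (present in
#' at least one of its master lists), the Venn regions implied by those sets,
#' the highly reproducible (HR) proteins (present in every master list of at
#' least one histotype), and the histotype-specific HR proteins (present in
#' all samples of exactly one histotype and absent from every other
#' histotype's lists).
#'
#' @slot universe character, all proteins identified anywhere in the study.
#' @slot identified named list, per-histotype identified accession sets.
#' @slot vennRegions named list, one accession set per Venn region; labels
#'   are histotype names joined with \code{"+"} in canonical order. Regions
#'   partition the universe.
#' @slot hrSet character, HR accessions.
#' @slot specificHR named list, per-histotype specific HR accession sets.
#' @slot commonAllSamples character, proteins present in every master list of
#'   every histotype.
#' @slot commonAtLeastOnce character, proteins identified at least once in
#'   every histotype.
#' @export
setClass("PresencePartition",
    slots = c(
        universe = "character",
        identified = "list",
        vennRegions = "list",
        hrSet = "character",
        specificHR = "list",
        commonAllSamples = "character",
        commonAtLeastOnce = "character"
    )
)

setValidity("PresencePartition", function(object) {
    msg <- character()
    regs <- object@vennRegions
    pooled <- unlist(regs, use.names = FALSE)
    if (anyDuplicated(pooled))
        msg <- c(msg, "venn regions must be pairwise disjoint")
    if (!setequal(pooled, object@universe))
        msg <- c(msg, "venn regions must cover the universe exactly")
    spec <- unlist(object@specificHR, use.names = FALSE)
    if (anyDuplicated(spec))
        msg <- c(msg, "specific HR sets must be pairwise disjoint")
    if (!all(spec %in% object@hrSet))
        msg <- c(msg, "specific HR sets must be subsets of the HR set")
    if (!all(object@commonAllSamples %in% object@commonAtLeastOnce))
        msg <- c(msg, "commonAllSamples must be within commonAtLeastOnce")
    if (!all(object@commonAllSamples %in% object@hrSet))
        msg <- c(msg, "commonAllSamples must be within the HR set")
    if (length(msg)) msg else TRUE
})
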