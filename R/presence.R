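## Presence/absence logic: Venn partition across histotypes, highly
## reproducible (HR) proteins, histotype-specific HR proteins, and
## serum/CSF source classification. "Identified in a sample" means present
## in that sample's master list, i.e. detected in at least one technical
## replicate.

#' Venn partition, HR selection and histotype-specific HR proteins
#'
#' Partitions the identified proteome by histotype membership. A protein
#' belongs to a histotype's identified set iff it appears (value > 0) in at
#' least one of that histotype's master lists. The Venn regions are labelled
#' by the histotype names joined with \code{"+"}, in canonical
#' (first-appearance) order, and partition the universe. The function also
#' computes the HR set (proteins present in every master list of at least
#' one histotype), the per-histotype specific HR sets (present in all
#' samples of one histotype, absent from every list of the others), the
#' proteins present in every sample of every histotype, and those identified
#' at least once per histotype.
#'
#' @param masters sample-level [SpcExperiment-class] from
#'   [buildMasterLists()]; at least two histotypes.
#' @return a [PresencePartition-class].
#' @export
vennPartition <- function(masters) {
    stopifnot(is(masters, "SpcExperiment"), spcLevel(masters) == "sample")
    cd <- as.data.frame(colData(masters))
    hts <- histotypes(masters)
    if (length(hts) < 2L)
        stop("validation error: at least two histotypes are required")
    m <- spc(masters) > 0
    identified <- lapply(hts, function(h) {
        rownames(m)[rowSums(m[, cd$histotype == h, drop = FALSE]) > 0]
    })
    names(identified) <- hts
    universe <- rownames(m)[rowSums(m) > 0]

    membership <- vapply(identified, function(s) universe %in% s,
                         logical(length(universe)))
    if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
    subsets <- .vennSubsets(hts)
    regions <- lapply(subsets, function(ss) {
        inside <- rowSums(membership[, ss, drop = FALSE]) == length(ss)
        outside <- rowSums(membership[, setdiff(hts, ss), drop = FALSE]) == 0
        universe[inside & outside]
    })
    names(regions) <- vapply(subsets, paste, character(1), collapse = "+")

    allSamplesBy <- lapply(hts, function(h) {
        rownames(m)[rowSums(m[, cd$histotype == h, drop = FALSE]) ==
                        sum(cd$histotype == h)]
    })
    names(allSamplesBy) <- hts
    hr <- sort(unique(unlist(allSamplesBy, use.names = FALSE)))
    specific <- lapply(hts, function(h) {
        others <- unlist(identified[setdiff(hts, h)], use.names = FALSE)
        sort(setdiff(allSamplesBy[[h]], others))
    })
    names(specific) <- hts
    commonAll <- rownames(m)[rowSums(m) == ncol(m)]
    commonOnce <- Reduce(intersect, identified)

    new("PresencePartition",
        universe = universe, identified = identified, vennRegions = regions,
        hrSet = hr, specificHR = specific,
        commonAllSamples = sort(commonAll), commonAtLeastOnce = sort(commonOnce))
}

## all non-empty subsets of the histotype labels, singletons first, in
## canonical order — the 2^n - 1 Venn region labels (7 for 3 histotypes)
.vennSubsets <- function(hts) {
    out <- list()
    for (k in seq_along(hts))
        out <- c(out, utils::combn(hts, k, simplify = FALSE))
    out
}

#' Select highly reproducible (HR) proteins
#'
#' A protein is HR iff there exists a histotype in whose every master list it
#' appears. Adding a detection never removes a protein from the HR set.
#'
#' @param masters sample-level [SpcExperiment-class].
#' @return character vector of HR accessions (sorted).
#' @export
selectHR <- function(masters) {
    stopifnot(is(masters, "SpcExperiment"), spcLevel(masters) == "sample")
    cd <- as.data.frame(colData(masters))
    m <- spc(masters) > 0
    hr <- lapply(histotypes(masters), function(h) {
        cols <- cd$histotype == h
        rownames(m)[rowSums(m[, cols, drop = FALSE]) == sum(cols)]
    })
    sort(unique(unlist(hr, use.names = FALSE)))
}

#' Histotype-specific HR proteins
#'
#' Proteins present in every master list of one histotype and absent from
#' every master list of all other histotypes.
#'
#' @param partition a [PresencePartition-class] from [vennPartition()].
#' @return named list of accession sets, one per histotype.
#' @export
histotypeSpecificHR <- function(partition) {
    stopifnot(is(partition, "PresencePartition"))
    partition@specificHR
}

#' @rdname PresencePartition-class
#' @export
setMethod("identifiedSets", "PresencePartition", function(x) x@identified)
#' @rdname PresencePartition-class
#' @export
setMethod("vennRegions", "PresencePartition", function(x) x@vennRegions)
#' @rdname PresencePartition-class
#' @export
setMethod("hrProteins", "PresencePartition", function(x) x@hrSet)
#' @rdname PresencePartition-class
#' @export
setMethod("specificHR", "PresencePartition", function(x) x@specificHR)
#' @rdname PresencePartition-class
#' @export
setMethod("commonAllSamples", "PresencePartition", function(x) x@commonAllSamples)
#' @rdname PresencePartition-class
#' @export
setMethod("commonAtLeastOnce", "PresencePartition", function(x) x@commonAtLeastOnce)

setMethod("show", "PresencePartition", function(object) {
    cat("PresencePartition over", length(object@universe), "proteins\n")
    sizes <- vapply(object@vennRegions, length, integer(1))
    cat("venn regions:",
        paste(names(sizes), sizes, sep = "=", collapse = ", "), "\n")
    cat("HR proteins:", length(object@hrSet), "| specific HR:",
        paste(names(object@specificHR),
              vapply(object@specificHR, length, integer(1)),
              sep = "=", collapse = ", "), "\n")
    cat("present in all samples:", length(object@commonAllSamples),
        "| identified in every histotype:",
        length(object@commonAtLeastOnce), "\n")
})

#' Classify proteins by presumptive fluid source
#'
#' Four-way classification against user-supplied reference compilations of
#' serum and cerebrospinal-fluid proteomes: \code{S} (serum only),
#' \code{CSF} (CSF only), \code{S+CSF} (both), \code{NS+NCSF} (neither).
#'
#' @param universe accession set to classify.
#' @param serumRef,csfRef reference accession sets.
#' @return named factor over the universe with the four class levels.
#' @export
classifySource <- function(universe, serumRef, csfRef) {
    inS <- universe %in% serumRef
    inC <- universe %in% csfRef
    cls <- ifelse(inS & inC, "S+CSF",
           ifelse(inS, "S", ifelse(inC, "CSF", "NS+NCSF")))
    factor(stats::setNames(cls, universe),
           levels = c("S", "CSF", "S+CSF", "NS+NCSF"))
}

#' Expand a tumor-specific presence table into a sample-level experiment
#'
#' Turns a per-histotype protein table (such as [loadTumorSpecificHR()])
#' into a sample-level [SpcExperiment-class] in which each protein is
#' present, at a constant value, in every sample of its own histotype and
#' absent everywhere else — the presence structure asserted by such tables.
#'
#' @param fixture data.frame with columns \code{histotype} and
#'   \code{accession}.
#' @param samplesPerHistotype named integer vector, samples per histotype
#'   (default \code{c(SM = 3, CS = 2, CG = 2)}).
#' @param value positive count assigned to present cells.
#' @return sample-level [SpcExperiment-class].
#' @export
#' @examples
#' part <- vennPartition(expandPresenceFixture(loadTumorSpecificHR()))
#' lengths(specificHR(part))
expandPresenceFixture <- function(fixture,
                                  samplesPerHistotype = c(SM = 3, CS = 2, CG = 2),
                                  value = 10) {
    stopifnot(all(c("histotype", "accession") %in% names(fixture)),
              !anyDuplicated(fixture$accession), value > 0)
    if (!all(fixture$histotype %in% names(samplesPerHistotype)))
        stop("validation error: fixture histotype missing from samplesPerHistotype")
    hts <- names(samplesPerHistotype)
    samples <- unlist(lapply(hts, function(h)
        paste0(h, seq_len(samplesPerHistotype[[h]]))), use.names = FALSE)
    ht_of <- rep(hts, samplesPerHistotype[hts])
    m <- matrix(0, nrow = nrow(fixture), ncol = length(samples),
                dimnames = list(fixture$accession, samples))
    for (i in seq_len(nrow(fixture)))
        m[i, ht_of == fixture$histotype[i]] <- value
    cdat <- data.frame(sample_id = samples, histotype = ht_of,
                       timepoint = unlist(lapply(samplesPerHistotype[hts],
                                                 seq_len), use.names = FALSE),
                       n_replicates = 1L, row.names = samples)
    SpcExperiment(m, colData = cdat, level = "sample")
}
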