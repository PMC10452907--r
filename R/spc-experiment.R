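#' Construct an SpcExperiment
#'
#' @param spc numeric matrix, proteins x columns, non-negative, with unique
#'   rownames (accessions) and colnames.
#' @param colData data.frame/DataFrame of column metadata.
#' @param level aggregation level, one of \code{"run"}, \code{"sample"},
#'   \code{"histotype"}.
#' @param rowData optional data.frame/DataFrame of protein metadata.
#' @return an [SpcExperiment-class] object.
#' @export
SpcExperiment <- function(spc, colData, level = "run", rowData = NULL) {
    spc <- as.matrix(spc)
    se <- if (is.null(rowData))
        SummarizedExperiment(assays = list(spc = spc),
                             colData = S4Vectors::DataFrame(colData))
    else
        SummarizedExperiment(assays = list(spc = spc),
                             colData = S4Vectors::DataFrame(colData),
                             rowData = S4Vectors::DataFrame(rowData))
    new("SpcExperiment", se, spcLevel = level)
}

#' @rdname SpcExperiment
#' @param x an \code{SpcExperiment}.
#' @export
setMethod("spcLevel", "SpcExperiment", function(x) x@spcLevel)

#' @describeIn SpcExperiment spectral-count matrix accessor.
#' @export
spc <- function(x) assay(x, "spc")

#' Canonical histotype order of an experiment
#'
#' First-appearance order of histotype labels in the column metadata.
#' @param x an \code{SpcExperiment} whose colData has a histotype column.
#' @return character vector of histotype labels.
#' @export
histotypes <- function(x) unique(as.character(colData(x)$histotype))

setMethod("show", "SpcExperiment", function(object) {
    cat("SpcExperiment (level: ", object@spcLevel, ")\n", sep = "")
    cat(nrow(object), " proteins x ", ncol(object), " ",
        object@spcLevel, "(s)\n", sep = "")
    if ("histotype" %in% names(colData(object)))
        cat("histotypes:", paste(histotypes(object), collapse = ", "), "\n")
    if (isTRUE(metadata(object)$normalized))
        cat("total-signal normalized (reference total ",
            format(metadata(object)$reference_total), ")\n", sep = "")
})

#' Assemble a run-level spectral-count matrix from per-run reports
#'
#' Builds the proteins x runs count matrix over the union of accessions seen
#' in any run (absence encoded as 0), with the manifest as column metadata.
#' Columns follow manifest order; rows follow first appearance across
#' reports in that order.
#'
#' @param reports list of run-report data.frames ([readRunReport()]); run ids
#'   are taken from each report's \code{run_id} attribute, or from list names.
#' @param manifest validated manifest ([readManifest()]); every report must
#'   be listed and every listed run must have a report.
#' @return run-level [SpcExperiment-class] with gene/description rowData.
#' @export
buildSpcMatrix <- function(reports, manifest) {
    manifest <- validateManifest(manifest)
    ids <- vapply(seq_along(reports), function(i) {
        id <- attr(reports[[i]], "run_id")
        if (is.null(id)) id <- names(reports)[i]
        if (is.null(id) || !nzchar(id))
            stop("validation error: report ", i, " has no run id")
        id
    }, character(1))
    if (anyDuplicated(ids))
        stop("validation error: duplicated run id among reports")
    names(reports) <- ids
    extra <- setdiff(ids, manifest$run_id)
    if (length(extra))
        stop("validation error: run(s) not in manifest: ",
             paste(extra, collapse = ", "))
    missing <- setdiff(manifest$run_id, ids)
    if (length(missing))
        stop("validation error: manifest run(s) without a report: ",
             paste(missing, collapse = ", "))
    reports <- reports[manifest$run_id]
    accs <- unique(unlist(lapply(reports, `[[`, "accession"),
                          use.names = FALSE))
    m <- matrix(0, nrow = length(accs), ncol = nrow(manifest),
                dimnames = list(accs, manifest$run_id))
    gene <- stats::setNames(rep("", length(accs)), accs)
    descr <- stats::setNames(rep("", length(accs)), accs)
    for (id in manifest$run_id) {
        rep_ <- reports[[id]]
        m[rep_$accession, id] <- rep_$spc
        fill <- !nzchar(gene[rep_$accession])
        gene[rep_$accession[fill]] <- rep_$gene[fill]
        fill <- !nzchar(descr[rep_$accession])
        descr[rep_$accession[fill]] <- rep_$description[fill]
    }
    SpcExperiment(m, colData = manifest, level = "run",
                  rowData = data.frame(gene = gene, description = descr,
                                       row.names = accs))
}
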