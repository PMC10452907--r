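## Reading and writing of run-level protein reports, study manifests, GMT
## pathway files and PPI edge lists. All files are tab-separated UTF-8 with a
## header row; the internal model is dialect-free.

#' Column-name dialects for run-level protein reports
#'
#' A dialect maps the internal field names to the column headers found in a
#' report file. Only \code{accession} and \code{spc} are required to resolve;
#' the remaining fields default to empty/missing when their column is absent.
#'
#' @param accession,gene,description,spc,mw_kda,pi column header carrying the
#'   corresponding field.
#' @return named character vector usable as the \code{dialect} argument of
#'   [readRunReport()].
#' @export
#' @examples
#' reportDialect()
#' pdDialect()
reportDialect <- function(accession = "accession", gene = "gene",
                          description = "description", spc = "spc",
                          mw_kda = "mw_kda", pi = "pi") {
    c(accession = accession, gene = gene, description = description,
      spc = spc, mw_kda = mw_kda, pi = pi)
}

#' @rdname reportDialect
#' @details `pdDialect()` matches a Proteome Discoverer 2.x protein export,
#'   where spectral counts are reported as PSM numbers.
#' @export
pdDialect <- function() {
    reportDialect(accession = "Accession", gene = "Gene Symbol",
                  description = "Description", spc = "# PSMs",
                  mw_kda = "MW [kDa]", pi = "calc. pI")
}

#' Read a single-run protein report
#'
#' Reads one LC-MS/MS run's protein table (accession, spectral count and
#' optional annotation columns). Duplicate accessions within a run are
#' collapsed by summing their spectral counts (with a warning), preserving
#' the run's total signal for normalization.
#'
#' @param path TSV file with a header row.
#' @param runId run identifier; defaults to the file name without extension.
#' @param dialect column-name mapping, see [reportDialect()].
#' @return data.frame with columns \code{accession}, \code{gene},
#'   \code{description}, \code{spc}, \code{mw_kda}, \code{pi}, rows in file
#'   order, and attribute \code{run_id}.
#' @export
readRunReport <- function(path, runId = sub("\\.[^.]*$", "", basename(path)),
                          dialect = reportDialect()) {
    stopifnot(is.character(runId), length(runId) == 1L, nzchar(runId))
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                             stringsAsFactors = FALSE, quote = "")
    for (f in c("accession", "spc")) {
        if (!dialect[[f]] %in% names(tab))
            stop("format error: required column '", dialect[[f]],
                 "' (", f, ") not found in ", path)
    }
    pick <- function(f, default) {
        if (!dialect[[f]] %in% names(tab)) return(rep(default, nrow(tab)))
        v <- tab[[dialect[[f]]]]
        if (is.character(default)) v[is.na(v)] <- default
        v
    }
    out <- data.frame(
        accession = as.character(tab[[dialect[["accession"]]]]),
        gene = as.character(pick("gene", "")),
        description = as.character(pick("description", "")),
        spc = as.numeric(tab[[dialect[["spc"]]]]),
        mw_kda = as.numeric(pick("mw_kda", NA_real_)),
        pi = as.numeric(pick("pi", NA_real_)),
        stringsAsFactors = FALSE
    )
    if (anyNA(out$spc))
        stop("validation error: non-numeric spc at row ",
             which(is.na(out$spc))[1L], " of ", path)
    if (any(out$spc < 0))
        stop("validation error: negative spc at row ",
             which(out$spc < 0)[1L], " of ", path)
    bad <- !is.na(out$pi) & (out$pi <= 0 | out$pi >= 14)
    if (any(bad))
        stop("validation error: pI outside (0, 14) at row ", which(bad)[1L])
    if (anyDuplicated(out$accession)) {
        dups <- unique(out$accession[duplicated(out$accession)])
        warning("collapsing ", length(dups),
                " duplicated accession(s) by summing spc in run ", runId)
        spc <- rowsum(out$spc, out$accession, reorder = FALSE)[, 1L]
        out <- out[!duplicated(out$accession), , drop = FALSE]
        out$spc <- spc[out$accession]
        rownames(out) <- NULL
    }
    attr(out, "run_id") <- runId
    out
}

#' @rdname readRunReport
#' @param report a run-report data.frame as returned by [readRunReport()].
#' @export
writeRunReport <- function(report, path) {
    utils::write.table(
        report[, c("accession", "gene", "description", "spc", "mw_kda", "pi")],
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a study manifest
#'
#' The manifest maps LC-MS/MS runs to biological samples, histotypes,
#' sequential timepoints and technical replicates. Histotype labels are
#' preserved verbatim; their canonical order is first appearance.
#'
#' @param path TSV file with columns \code{run_id}, \code{sample_id},
#'   \code{histotype}, \code{timepoint}, \code{replicate}.
#' @return validated manifest data.frame.
#' @export
readManifest <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                             stringsAsFactors = FALSE, quote = "")
    validateManifest(tab)
}

#' @rdname readManifest
#' @param manifest a manifest data.frame (e.g. built in code).
#' @export
validateManifest <- function(manifest) {
    req <- c("run_id", "sample_id", "histotype", "timepoint", "replicate")
    miss <- setdiff(req, names(manifest))
    if (length(miss))
        stop("format error: manifest misses column(s): ",
             paste(miss, collapse = ", "))
    if (nrow(manifest) == 0L)
        stop("validation error: manifest is empty")
    if (anyDuplicated(manifest$run_id))
        stop("validation error: duplicated run_id: ",
             manifest$run_id[duplicated(manifest$run_id)][1L])
    manifest$timepoint <- as.integer(manifest$timepoint)
    manifest$replicate <- as.integer(manifest$replicate)
    if (anyNA(manifest$timepoint) || any(manifest$timepoint < 1L))
        stop("validation error: timepoint must be an integer >= 1")
    if (anyNA(manifest$replicate) || any(manifest$replicate < 1L))
        stop("validation error: replicate must be an integer >= 1")
    per <- unique(manifest[, c("sample_id", "histotype", "timepoint")])
    if (anyDuplicated(per$sample_id)) {
        bad <- per$sample_id[duplicated(per$sample_id)][1L]
        stop("validation error: sample '", bad,
             "' maps to more than one histotype/timepoint")
    }
    manifest[, req]
}

#' Read and write GMT pathway annotation files
#'
#' Standard GMT: one pathway per line, tab-separated fields
#' \code{id}, \code{description}, then one or more members. Members are
#' deduplicated on read.
#'
#' @param path GMT file.
#' @return named list of character member vectors, with a
#'   \code{"descriptions"} attribute (named character vector).
#' @export
readGMT <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("format error: empty GMT file ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("format error: GMT line ", which(nf < 3L)[1L],
             " has fewer than 3 fields")
    ids <- vapply(fields, `[[`, character(1), 1L)
    if (anyDuplicated(ids))
        stop("validation error: duplicated pathway id: ",
             ids[duplicated(ids)][1L])
    members <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(members) <- ids
    descr <- vapply(fields, `[[`, character(1), 2L)
    names(descr) <- ids
    attr(members, "descriptions") <- descr
    members
}

#' @rdname readGMT
#' @param pathways named list of member vectors (optionally with a
#'   \code{"descriptions"} attribute).
#' @export
writeGMT <- function(pathways, path) {
    descr <- attr(pathways, "descriptions")
    if (is.null(descr)) descr <- setNames(rep("", length(pathways)),
                                          names(pathways))
    lines <- vapply(names(pathways), function(id) {
        paste(c(id, descr[[id]], pathways[[id]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a PPI edge list with per-channel confidence scores
#'
#' @param path TSV with columns \code{protein_a}, \code{protein_b},
#'   \code{channel} (\code{"databases"} or \code{"experiments"}) and
#'   \code{score} in \eqn{[0, 1]}.
#' @return data.frame of edges; self-edges are dropped (with a warning).
#' @export
readPpiEdges <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                             stringsAsFactors = FALSE, quote = "")
    req <- c("protein_a", "protein_b", "channel", "score")
    miss <- setdiff(req, names(tab))
    if (length(miss))
        stop("format error: edge list misses column(s): ",
             paste(miss, collapse = ", "))
    tab$score <- as.numeric(tab$score)
    if (anyNA(tab$score) || any(tab$score < 0 | tab$score > 1))
        stop("validation error: scores must be numeric in [0, 1]")
    if (!all(tab$channel %in% c("databases", "experiments")))
        stop("validation error: channel must be 'databases' or 'experiments'")
    self <- tab$protein_a == tab$protein_b
    if (any(self)) {
        warning("dropping ", sum(self), " self-edge(s)")
        tab <- tab[!self, , drop = FALSE]
    }
    rownames(tab) <- NULL
    tab[, req]
}

#' Packaged reference set of tumor-specific highly reproducible proteins
#'
#' Returns the published worked example bundled with the package: 31
#' proteins from a three-histotype sequential cystic-fluid study (secretory
#' meningioma SM, cystic schwannoma CS, cystic high-grade glioma CG), each
#' identified in every sample of exactly one histotype and in no sample of
#' the others. The per-histotype split is 4 (SM), 8 (CS) and 19 (CG).
#'
#' @return data.frame with columns \code{histotype}, \code{accession},
#'   \code{gene}, \code{protein}, \code{mw_kda}, \code{pi}.
#' @export
#' @examples
#' tab <- loadTumorSpecificHR()
#' table(tab$histotype)
loadTumorSpecificHR <- function() {
    path <- system.file("extdata", "tumor_specific_hr_proteins.tsv",
                        package = "cystflow", mustWork = TRUE)
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, quote = "")
}
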