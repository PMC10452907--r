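## One-call pipeline driver: normalization -> master lists -> histotype
## averaging -> presence partition / HR -> DAve-DCI calling ->
## representation -> bubbles -> ORA -> network -> stability statistics,
## with every effective threshold echoed in the summary.

#' Run the full spectral-count differential pipeline
#'
#' Executes all stages in order on run-level reports plus a manifest, and
#' optionally writes the result tables and a machine-readable summary to
#' \code{outDir}. The overrepresentation query follows the study design:
#' proteins \emph{not} identified in every histotype, tested within the
#' universe of all identified proteins.
#'
#' @param reports named list of run-report data.frames ([readRunReport()]
#'   or [simulateStudy()]).
#' @param manifest study manifest.
#' @param pathways optional pathway annotation ([readGMT()]); enables the
#'   bubble summary and the overrepresentation analysis.
#' @param selectedPathways pathway ids for the bubble summary (default:
#'   all).
#' @param edges optional PPI edge list ([readPpiEdges()]); enables network
#'   annotation.
#' @param serumRef,csfRef optional serum/CSF reference accession sets;
#'   enable source classification and the chi-square homogeneity test.
#' @param comparisons ordered histotype pairs for DEP calling (default all
#'   pairs in canonical order).
#' @param daveThr,dciThr DEP thresholds (defaults 0.4, 5).
#' @param repCutoff up/down boundary on the relative scale (default 50).
#' @param dbThr,expThr PPI channel thresholds (defaults 0.3, 0.15).
#' @param alpha,fdrThr ORA significance thresholds (defaults 0.05, 0.05).
#' @param outDir optional output directory for TSV tables and
#'   \code{summary.json}.
#' @return list with the stage results: \code{runs}, \code{normalized},
#'   \code{masters}, \code{histotype}, \code{partition}, \code{deps},
#'   \code{dep_accessions}, \code{representation}, \code{bubbles},
#'   \code{enrichment}, \code{network}, \code{stability},
#'   \code{source_class}, \code{homogeneity}, \code{summary}.
#' @export
runPipeline <- function(reports, manifest, pathways = NULL,
                        selectedPathways = NULL, edges = NULL,
                        serumRef = NULL, csfRef = NULL, comparisons = NULL,
                        daveThr = 0.4, dciThr = 5, repCutoff = 50,
                        dbThr = 0.3, expThr = 0.15, alpha = 0.05,
                        fdrThr = 0.05, outDir = NULL) {
    runs <- buildSpcMatrix(reports, manifest)
    normalized <- normalizeTotalSignal(runs)
    masters <- buildMasterLists(normalized)
    ht <- averageHistotype(masters)
    partition <- vennPartition(masters)
    hr <- hrProteins(partition)
    htHR <- ht[intersect(rownames(ht), hr), ]
    deps <- callDEPs(htHR, comparisons, daveThr, dciThr)
    representation <- relativeScale(htHR, repCutoff)

    bubbles <- enrichment <- network <- sourceClass <- homogeneity <- NULL
    if (!is.null(pathways)) {
        sel <- if (is.null(selectedPathways)) names(pathways)
               else selectedPathways
        bubbles <- bubbleSummary(representation, pathways, sel)
        query <- setdiff(partition@universe, commonAtLeastOnce(partition))
        enrichment <- hypergeomORA(query, pathways, partition@universe,
                                   alpha = alpha, fdrThr = fdrThr)
    }
    if (!is.null(edges)) {
        filtered <- filterPpiEdges(edges, dbThr, expThr)
        network <- annotateNetwork(hr, deps, specificHR(partition),
                                   representation, filtered)
    }
    stability <- stabilityAnova(masters)
    if (!is.null(serumRef) && !is.null(csfRef)) {
        sourceClass <- classifySource(partition@universe, serumRef, csfRef)
        observed <- vapply(identifiedSets(partition), function(s)
            table(sourceClass[s]), integer(nlevels(sourceClass)))
        observed <- observed[rowSums(observed) > 0, , drop = FALSE]
        homogeneity <- chiSquareHomogeneity(observed)
    }

    summary <- list(
        n_runs = ncol(runs), n_samples = ncol(masters),
        n_histotypes = ncol(ht),
        n_universe = length(partition@universe),
        venn_regions = lapply(vennRegions(partition), length),
        n_common_all_samples = length(commonAllSamples(partition)),
        n_common_at_least_once = length(commonAtLeastOnce(partition)),
        n_hr = length(hr),
        n_specific_hr = lapply(specificHR(partition), length),
        n_dep = length(depAccessions(deps)),
        thresholds = list(dave = daveThr, dci = dciThr,
                          rep_cutoff = repCutoff, db = dbThr, exp = expThr,
                          alpha = alpha, fdr = fdrThr))

    result <- list(runs = runs, normalized = normalized, masters = masters,
                   histotype = ht, partition = partition, deps = deps,
                   dep_accessions = depAccessions(deps),
                   representation = representation, bubbles = bubbles,
                   enrichment = enrichment, network = network,
                   stability = stability, source_class = sourceClass,
                   homogeneity = homogeneity, summary = summary)
    if (!is.null(outDir)) .writeResults(result, outDir)
    result
}

.writeTsv <- function(x, path) {
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], round, digits = 3L)
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.writeResults <- function(result, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    longSpc <- function(se, col) {
        m <- spc(se)
        d <- data.frame(id = rep(colnames(m), each = nrow(m)),
                        accession = rep(rownames(m), times = ncol(m)),
                        spc_norm = as.vector(m))
        names(d)[1L] <- col
        d[d$spc_norm > 0, , drop = FALSE]
    }
    .writeTsv(longSpc(result$masters, "sample_id"),
              file.path(outDir, "master_lists.tsv"))
    .writeTsv(longSpc(result$histotype, "histotype"),
              file.path(outDir, "histotype_lists.tsv"))
    .writeTsv(result$deps, file.path(outDir, "deps.tsv"))
    .writeTsv(result$representation, file.path(outDir, "representation.tsv"))
    .writeTsv(result$stability, file.path(outDir, "stability.tsv"))
    if (!is.null(result$bubbles))
        .writeTsv(result$bubbles, file.path(outDir, "bubbles.tsv"))
    if (!is.null(result$enrichment))
        .writeTsv(result$enrichment, file.path(outDir, "enrichment.tsv"))
    if (!is.null(result$network)) {
        .writeTsv(result$network$nodes, file.path(outDir, "nodes.tsv"))
        .writeTsv(result$network$edges, file.path(outDir, "edges.tsv"))
    }
    jsonlite::write_json(result$summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(outDir)
}
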