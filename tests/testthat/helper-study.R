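# Builders for tiny in-code fixtures.

# run-level SpcExperiment straight from a matrix; colData defaults to a
# minimal manifest with one sample per run unless a manifest is given
runSE <- function(m, manifest = NULL) {
    if (is.null(manifest))
        manifest <- data.frame(run_id = colnames(m), sample_id = colnames(m),
                               histotype = "H", timepoint = 1L,
                               replicate = seq_len(ncol(m)))
    SpcExperiment(m, colData = manifest, level = "run")
}

# sample-level SpcExperiment (master lists) from a matrix + histotype vector
sampleSE <- function(m, histotype) {
    stopifnot(length(histotype) == ncol(m))
    cd <- data.frame(sample_id = colnames(m), histotype = histotype,
                     timepoint = stats::ave(seq_len(ncol(m)), histotype,
                                            FUN = seq_along),
                     n_replicates = 1L, row.names = colnames(m))
    SpcExperiment(m, colData = cd, level = "sample")
}

# histotype-level SpcExperiment from a matrix whose columns are histotypes
htSE <- function(m) {
    cd <- data.frame(histotype = colnames(m), n_samples = 1L,
                     row.names = colnames(m))
    SpcExperiment(m, colData = cd, level = "histotype")
}

# presence-only master lists: `sets` is a named list sample_id -> accessions,
# `histotype` a parallel vector of the samples' histotypes
presenceSE <- function(sets, histotype, value = 5) {
    accs <- sort(unique(unlist(sets, use.names = FALSE)))
    m <- vapply(sets, function(s) as.numeric(accs %in% s) * value,
                numeric(length(accs)))
    rownames(m) <- accs
    sampleSE(m, histotype)
}

# a run-report data.frame as readRunReport() would return
reportDF <- function(accession, spc, run_id, gene = "") {
    out <- data.frame(accession = accession, gene = gene, description = "",
                      spc = as.numeric(spc), mw_kda = NA_real_,
                      pi = NA_real_, stringsAsFactors = FALSE)
    attr(out, "run_id") <- run_id
    out
}

# exhaustive-enumeration oracle for the upper-tail hypergeometric
# probability: over all C(N, n) equally likely query draws from the
# universe, the fraction with overlap >= k
oracleUpperHyper <- function(universe, members, n, k) {
    draws <- utils::combn(universe, n, simplify = FALSE)
    mean(vapply(draws, function(d) length(intersect(d, members)) >= k,
                logical(1)))
}

# small simulated study used by several suites
smallConfig <- function(seed = 1L, ...) {
    simulationConfig(nCore = 25L, nSpecific = c(2L, 3L, 4L), nDep = 8L,
                     seed = seed, ...)
}
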