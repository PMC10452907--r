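## Synthetic spectral-count studies with known ground truth. The generator
## mirrors the design the analysis assumes: three histotypes sampled
## sequentially (3 + 2 + 2 samples, two technical replicates each, 14
## runs), a shared high-abundance plasma/CSF-like core, histotype-specific
## proteins absent elsewhere (structural zeros), planted fold-change
## proteins, count noise and abundance-dependent dropout.

#' Configuration for a simulated spectral-count study
#'
#' Defaults reproduce the study design the pipeline targets: histotypes SM,
#' CS, CG with 3/2/2 sequential samples and 2 technical replicates (14
#' runs); 60 shared core proteins with mean spectral counts uniform in
#' 20-200; 4/8/19 histotype-specific proteins at 4-20; 20 planted
#' differential proteins (a subset of the core) with fold change 3 in a
#' designated histotype; Poisson counts with a logistic dropout in log mean
#' abundance emulating sporadic low-abundance identifications.
#'
#' @param histotypes histotype labels.
#' @param samplesPerHistotype integer vector, samples per histotype.
#' @param replicatesPerSample technical replicates per sample.
#' @param nCore number of shared core proteins.
#' @param coreAbundance range of core mean spectral counts.
#' @param nSpecific integer vector, specific proteins per histotype.
#' @param specificAbundance range of specific-protein mean counts.
#' @param nDep number of planted differential proteins (drawn from the
#'   core; must not exceed \code{nCore}).
#' @param depFold fold change applied in the designated histotype (> 1).
#' @param noise \code{"poisson"} or \code{"negative_binomial"}.
#' @param nbDispersion NB dispersion (variance \eqn{\mu + \phi \mu^2}).
#' @param dropoutMid,dropoutSlope logistic dropout parameters: a protein
#'   with mean \eqn{\mu} is zeroed in a replicate with probability
#'   \eqn{1/(1 + (\mu/mid)^{slope})} — 0.5 at \eqn{\mu = mid}, vanishing
#'   for abundant proteins.
#' @param seed integer seed; the same seed reproduces the study exactly.
#' @return validated config (classed list).
#' @export
simulationConfig <- function(histotypes = c("SM", "CS", "CG"),
                             samplesPerHistotype = c(3L, 2L, 2L),
                             replicatesPerSample = 2L,
                             nCore = 60L,
                             coreAbundance = c(20, 200),
                             nSpecific = c(4L, 8L, 19L),
                             specificAbundance = c(4, 20),
                             nDep = 20L,
                             depFold = 3,
                             noise = c("poisson", "negative_binomial"),
                             nbDispersion = 0.1,
                             dropoutMid = 1,
                             dropoutSlope = 2,
                             seed = 1L) {
    noise <- match.arg(noise)
    cfg <- list(histotypes = histotypes,
                samplesPerHistotype = as.integer(samplesPerHistotype),
                replicatesPerSample = as.integer(replicatesPerSample),
                nCore = as.integer(nCore), coreAbundance = coreAbundance,
                nSpecific = as.integer(nSpecific),
                specificAbundance = specificAbundance,
                nDep = as.integer(nDep), depFold = depFold, noise = noise,
                nbDispersion = nbDispersion, dropoutMid = dropoutMid,
                dropoutSlope = dropoutSlope, seed = as.integer(seed))
    with(cfg, {
        if (length(histotypes) < 2L || anyDuplicated(histotypes))
            stop("validation error: need >= 2 distinct histotypes")
        if (length(samplesPerHistotype) != length(histotypes) ||
            any(samplesPerHistotype < 1L))
            stop("validation error: samplesPerHistotype must give >= 1 per histotype")
        if (length(nSpecific) != length(histotypes) || any(nSpecific < 0L))
            stop("validation error: nSpecific must be non-negative per histotype")
        if (replicatesPerSample < 1L || nCore < 1L)
            stop("validation error: counts must be positive")
        if (nDep > nCore)
            stop("validation error: nDep must not exceed nCore")
        if (depFold <= 1)
            stop("validation error: depFold must be > 1")
        if (diff(coreAbundance) < 0 || coreAbundance[1] <= 0 ||
            diff(specificAbundance) < 0 || specificAbundance[1] <= 0)
            stop("validation error: abundance ranges must be positive and ordered")
    })
    structure(cfg, class = "SimulationConfig")
}

#' Simulate a complete spectral-count study
#'
#' Draws true per-histotype mean abundances (core means shared, specific
#' means zero outside the owner, planted differential means scaled by
#' \code{depFold} in the designated histotype), then generates integer
#' spectral counts per run from the configured noise model and zeroes each
#' (protein, replicate) cell with the abundance-dependent dropout
#' probability. Also emits a pathway annotation in which one planted
#' pathway is drawn predominantly from differential/specific proteins and
#' decoy pathways from unperturbed core proteins. Byte-identical for a
#' fixed seed; per-run draws use seeds derived from the global one, so a
#' single run is reproducible in isolation.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{reports} (named list of run-report data.frames),
#'   \code{manifest}, \code{truth} (one row per protein: accession, gene,
#'   tier core/specific/dep, owner histotype, per-histotype true means;
#'   attributes \code{planted_pathway} and \code{planted_members}),
#'   \code{pathways} and \code{config}.
#' @export
simulateStudy <- function(config = simulationConfig()) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    hts <- config$histotypes
    nht <- length(hts)

    core_acc <- sprintf("CORE%04d", seq_len(config$nCore))
    core_mu <- stats::runif(config$nCore, config$coreAbundance[1],
                            config$coreAbundance[2])
    dep_idx <- sort(sample.int(config$nCore, config$nDep))
    dep_owner <- hts[(seq_along(dep_idx) - 1L) %% nht + 1L]

    spec_acc <- unlist(lapply(seq_along(hts), function(i)
        sprintf("%sSP%03d", hts[i], seq_len(config$nSpecific[i]))),
        use.names = FALSE)
    spec_owner <- rep(hts, config$nSpecific)
    spec_mu <- stats::runif(length(spec_acc), config$specificAbundance[1],
                            config$specificAbundance[2])

    acc <- c(core_acc, spec_acc)
    tier <- c(ifelse(seq_len(config$nCore) %in% dep_idx, "dep", "core"),
              rep("specific", length(spec_acc)))
    owner <- c(character(config$nCore), spec_owner)
    owner[dep_idx] <- dep_owner
    owner[owner == ""] <- NA_character_

    mu <- matrix(0, nrow = length(acc), ncol = nht,
                 dimnames = list(acc, hts))
    mu[seq_len(config$nCore), ] <- core_mu
    for (j in seq_along(dep_idx))
        mu[dep_idx[j], dep_owner[j]] <- core_mu[dep_idx[j]] * config$depFold
    for (j in seq_along(spec_acc))
        mu[config$nCore + j, spec_owner[j]] <- spec_mu[j]

    manifest <- do.call(rbind, lapply(seq_along(hts), function(i) {
        do.call(rbind, lapply(seq_len(config$samplesPerHistotype[i]), function(s) {
            sid <- paste0(hts[i], s)
            data.frame(run_id = paste0(sid, "_r",
                                       seq_len(config$replicatesPerSample)),
                       sample_id = sid, histotype = hts[i], timepoint = s,
                       replicate = seq_len(config$replicatesPerSample),
                       stringsAsFactors = FALSE)
        }))
    }))
    rownames(manifest) <- NULL

    gene <- paste0("G", acc)
    reports <- lapply(seq_len(nrow(manifest)), function(j) {
        set.seed((config$seed * 7919L + j) %% 2147483647L)
        mu_j <- mu[, manifest$histotype[j]]
        counts <- if (config$noise == "poisson") stats::rpois(length(mu_j), mu_j)
                  else stats::rnbinom(length(mu_j), mu = mu_j,
                                      size = 1 / config$nbDispersion)
        pdrop <- ifelse(mu_j > 0,
                        stats::plogis(config$dropoutSlope *
                                      (log(config$dropoutMid) - log(mu_j))), 1)
        counts[stats::runif(length(counts)) < pdrop] <- 0L
        keep <- counts > 0
        out <- data.frame(accession = acc[keep], gene = gene[keep],
                          description = "", spc = as.numeric(counts[keep]),
                          mw_kda = NA_real_, pi = NA_real_,
                          stringsAsFactors = FALSE)
        attr(out, "run_id") <- manifest$run_id[j]
        out
    })
    names(reports) <- manifest$run_id

    set.seed((config$seed * 7919L + nrow(manifest) + 1L) %% 2147483647L)
    interesting <- acc[tier != "core"]
    filler <- acc[tier == "core"]
    planted <- c(sample(interesting, min(18L, length(interesting))),
                 sample(filler, min(3L, length(filler))))
    pathways <- c(list(planted_pathway = planted),
                  lapply(seq_len(10L), function(i)
                      sample(filler, min(12L, length(filler)))))
    names(pathways) <- c("planted_pathway", sprintf("decoy_%02d", 1:10))
    attr(pathways, "descriptions") <- stats::setNames(
        c("planted enriched set", rep("decoy set", 10L)), names(pathways))

    truth <- data.frame(accession = acc, gene = gene, tier = tier,
                        owner = owner, stringsAsFactors = FALSE)
    for (h in hts) truth[[paste0("mean_", h)]] <- mu[, h]
    attr(truth, "planted_pathway") <- "planted_pathway"
    attr(truth, "planted_members") <- planted

    list(reports = reports, manifest = manifest, truth = truth,
         pathways = pathways, config = config)
}

#' Write a simulated study to disk
#'
#' Emits one run-report TSV per run, plus \code{manifest.tsv},
#' \code{truth.tsv} and \code{pathways.gmt}.
#'
#' @param study result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeStudy <- function(study, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(study$reports))
        writeRunReport(study$reports[[id]], file.path(dir, paste0(id, ".tsv")))
    utils::write.table(study$manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(study$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeGMT(study$pathways, file.path(dir, "pathways.gmt"))
    invisible(dir)
}

#' Score pipeline output against simulation ground truth
#'
#' A protein is \emph{truly differential} when its true means differ
#' between at least one histotype pair (planted fold-change proteins and
#' histotype-specific proteins); a called DEP outside that set is a false
#' discovery. Sensitivity for the planted differential tier is the fraction
#' of \code{tier == "dep"} proteins recovered.
#'
#' @param truth truth table from [simulateStudy()].
#' @param depsCalled character vector of called DEP accessions.
#' @param specificCalled optional named list of called histotype-specific
#'   sets.
#' @param enrichment optional ORA result ([hypergeomORA()]), used to check
#'   whether the planted pathway is the top hit.
#' @return list with components \code{dep} (sensitivity, fdp, n_called),
#'   \code{specific} (per-histotype sensitivity) and
#'   \code{planted_pathway_top} (logical or NA). Sensitivities are NA when
#'   nothing was planted.
#' @export
evaluateRecovery <- function(truth, depsCalled, specificCalled = NULL,
                             enrichment = NULL) {
    meanCols <- grep("^mean_", names(truth), value = TRUE)
    mu <- as.matrix(truth[, meanCols])
    trulyDiff <- truth$accession[apply(mu, 1L, function(v) any(v != v[1L]))]
    planted <- truth$accession[truth$tier == "dep"]
    sens <- if (length(planted)) mean(planted %in% depsCalled) else NA_real_
    fdp <- if (length(depsCalled))
        mean(!depsCalled %in% trulyDiff) else 0
    spec <- NULL
    if (!is.null(specificCalled)) {
        spec <- vapply(names(specificCalled), function(h) {
            truthSet <- truth$accession[truth$tier == "specific" &
                                        !is.na(truth$owner) & truth$owner == h]
            if (!length(truthSet)) return(NA_real_)
            mean(truthSet %in% specificCalled[[h]])
        }, numeric(1))
    }
    top <- NA
    if (!is.null(enrichment) && nrow(enrichment))
        top <- enrichment$pathway[1L] == attr(truth, "planted_pathway")
    list(dep = list(sensitivity = sens, fdp = fdp,
                    n_called = length(depsCalled)),
         specific = spec, planted_pathway_top = top)
}
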