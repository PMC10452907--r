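test_that("the default design yields 14 runs over 7 samples", {
    study <- simulateStudy(simulationConfig(seed = 99))
    expect_equal(length(study$reports), 14L)
    expect_equal(nrow(study$manifest), 14L)
    expect_equal(length(unique(study$manifest$sample_id)), 7L)
    expect_equal(as.integer(table(study$manifest$histotype)[c("SM", "CS", "CG")]),
                 c(6L, 4L, 4L))
    # truth covers every simulated protein exactly once
    expect_equal(anyDuplicated(study$truth$accession), 0L)
    expect_equal(nrow(study$truth), 60L + 4L + 8L + 19L)
    expect_equal(as.integer(table(study$truth$tier)[c("core", "dep", "specific")]),
                 c(40L, 20L, 31L))
})

test_that("the same seed reproduces the study exactly; different seeds differ", {
    s1 <- simulateStudy(smallConfig(seed = 5L))
    s2 <- simulateStudy(smallConfig(seed = 5L))
    expect_identical(s1, s2)
    s3 <- simulateStudy(smallConfig(seed = 6L))
    expect_false(identical(s1$reports, s3$reports))
})

test_that("infeasible configurations are rejected", {
    expect_error(simulationConfig(nDep = 100, nCore = 50), "nDep")
    expect_error(simulationConfig(depFold = 1), "depFold")
    expect_error(simulationConfig(histotypes = c("A", "A")), "distinct")
    expect_error(simulationConfig(nSpecific = c(1, 2)), "nSpecific")
    expect_error(simulationConfig(coreAbundance = c(5, 2)), "abundance")
})

test_that("histotype-specific proteins have structural zeros outside the owner", {
    study <- simulateStudy(smallConfig(seed = 12L))
    spec <- study$truth[study$truth$tier == "specific", ]
    for (i in seq_len(nrow(spec))) {
        runsElsewhere <- study$manifest$run_id[
            study$manifest$histotype != spec$owner[i]]
        for (r in runsElsewhere)
            expect_false(spec$accession[i] %in%
                             study$reports[[r]]$accession)
    }
})

test_that("planted differential proteins carry the configured fold change", {
    cfg <- smallConfig(seed = 31L)
    study <- simulateStudy(cfg)
    dep <- study$truth[study$truth$tier == "dep", ]
    mu <- as.matrix(dep[, paste0("mean_", cfg$histotypes)])
    for (i in seq_len(nrow(dep))) {
        own <- which(cfg$histotypes == dep$owner[i])
        expect_equal(unname(mu[i, own] / mu[i, -own][1]), cfg$depFold)
        expect_equal(unname(mu[i, -own][1]), unname(mu[i, -own][2]))
    }
})

test_that("recovery scoring reports sensitivity and FDP as defined", {
    truth <- data.frame(accession = c("A", "B", "C", "D"),
                        tier = c("dep", "dep", "core", "specific"),
                        owner = c("SM", "SM", NA, "CS"),
                        mean_SM = c(30, 30, 10, 0), mean_CS = c(10, 10, 10, 8))
    attr(truth, "planted_pathway") <- "pw"
    all_rec <- evaluateRecovery(truth, depsCalled = c("A", "B"))
    expect_equal(all_rec$dep$sensitivity, 1)
    expect_equal(all_rec$dep$fdp, 0)
    half <- evaluateRecovery(truth, depsCalled = "A")
    expect_equal(half$dep$sensitivity, 0.5)
    # a called core protein is a false discovery, a specific one is not
    noisy <- evaluateRecovery(truth, depsCalled = c("A", "C", "D"))
    expect_equal(noisy$dep$fdp, 1 / 3)
    none_planted <- truth[truth$tier == "core", , drop = FALSE]
    attr(none_planted, "planted_pathway") <- "pw"
    expect_true(is.na(evaluateRecovery(none_planted, character(0))$dep$sensitivity))
    # top-pathway check
    enr <- data.frame(pathway = c("pw", "decoy"), p_value = c(0.001, 0.8))
    expect_true(evaluateRecovery(truth, "A", enrichment = enr)$planted_pathway_top)
})

test_that("raising the planted fold change never hurts expected sensitivity", {
    folds <- c(2, 3, 5)
    sens <- sapply(folds, function(f) {
        mean(sapply(1:5, function(seed) {
            study <- simulateStudy(smallConfig(seed = seed, depFold = f))
            res <- runPipeline(study$reports, study$manifest)
            evaluateRecovery(study$truth, res$dep_accessions)$dep$sensitivity
        }))
    })
    # paired over the same seeds; allow minimal sampling slack
    expect_true(all(diff(sens) >= -0.02))
})

test_that("a written study round-trips through the file readers", {
    study <- simulateStudy(smallConfig(seed = 8L))
    dir <- withr::local_tempdir()
    writeStudy(study, dir)
    man <- readManifest(file.path(dir, "manifest.tsv"))
    expect_equal(man, study$manifest, ignore_attr = TRUE)
    rep1 <- readRunReport(file.path(dir, "SM1_r1.tsv"))
    expect_equal(rep1$spc, study$reports$SM1_r1$spc)
    pws <- readGMT(file.path(dir, "pathways.gmt"))
    expect_equal(lapply(pws, sort), lapply(study$pathways, sort),
                 ignore_attr = TRUE)
})
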