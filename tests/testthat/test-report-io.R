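test_that("run reports read back in file order with totals preserved", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("accession\tspc", "P1\t10", "P2\t0", "P3\t5"), path)
    rep_ <- readRunReport(path, runId = "r1")
    expect_equal(rep_$accession, c("P1", "P2", "P3"))
    expect_equal(sum(rep_$spc), 15)
    expect_equal(attr(rep_, "run_id"), "r1")
})

test_that("duplicate accessions are collapsed by summing spc, with a warning", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("accession\tspc", "P1\t4", "P2\t1", "P1\t6"), path)
    expect_warning(rep_ <- readRunReport(path, runId = "r1"), "duplicated")
    expect_equal(nrow(rep_), 2L)
    expect_equal(rep_$spc[rep_$accession == "P1"], 10)
})

test_that("malformed run reports are rejected with informative errors", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("accession\tcount", "P1\t10"), path)
    expect_error(readRunReport(path), "spc")
    writeLines(c("accession\tspc", "P1\t10", "P2\t-3"), path)
    expect_error(readRunReport(path), "negative spc at row 2")
})

test_that("Proteome Discoverer dialect maps export headers", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("Accession\tGene Symbol\tDescription\t# PSMs\tMW [kDa]\tcalc. pI",
                 "P1\tALB\tAlbumin\t42\t69.3\t5.92"), path)
    rep_ <- readRunReport(path, dialect = pdDialect())
    expect_equal(rep_$spc, 42)
    expect_equal(rep_$gene, "ALB")
    expect_equal(rep_$mw_kda, 69.3)
})

test_that("run reports round-trip through write/read unchanged", {
    rep_ <- reportDF(c("P1", "P2", "Q9"), c(10, 0.5, 7), "runA",
                     gene = c("G1", "G2", "G3"))
    rep_$mw_kda <- c(10.5, NA, 99.1)
    rep_$pi <- c(5.5, 7.01, NA)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeRunReport(rep_, path)
    back <- readRunReport(path, runId = "runA")
    expect_equal(back, rep_, ignore_attr = TRUE)
})

test_that("manifests validate structure and sample uniqueness", {
    path <- withr::local_tempfile(fileext = ".tsv")
    study <- simulateStudy(smallConfig())
    utils::write.table(study$manifest, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    man <- readManifest(path)
    expect_equal(nrow(man), 14L)
    expect_equal(length(unique(man$sample_id)), 7L)

    writeLines("run_id\tsample_id\thistotype\ttimepoint\treplicate", path)
    expect_error(readManifest(path), "empty")

    bad <- data.frame(run_id = c("r1", "r2"), sample_id = "S1",
                      histotype = c("SM", "CS"), timepoint = 1L,
                      replicate = 1:2)
    expect_error(validateManifest(bad), "more than one histotype")
    bad2 <- data.frame(run_id = c("r1", "r1"), sample_id = c("S1", "S2"),
                       histotype = "SM", timepoint = 1L, replicate = 1L)
    expect_error(validateManifest(bad2), "duplicated run_id")
})

test_that("GMT files parse with member dedup and round-trip identically", {
    path <- withr::local_tempfile(fileext = ".gmt")
    writeLines(c("PW1\tdesc\tA\tB\tA", "PW2\tother\tC"), path)
    pws <- readGMT(path)
    expect_equal(length(pws), 2L)
    expect_equal(pws$PW1, c("A", "B"))

    out <- withr::local_tempfile(fileext = ".gmt")
    writeGMT(pws, out)
    expect_equal(readGMT(out), pws)

    writeLines("PW1\tdesc", path)
    expect_error(readGMT(path), "fewer than 3")
})

test_that("readGMT agrees with fgsea's GMT parser on the packaged fixture", {
    path <- system.file("extdata", "functional_categories_synthetic.gmt",
                        package = "cystflow")
    mine <- readGMT(path)
    ref <- fgsea::gmtPathways(path)
    expect_equal(length(mine), 13L)
    expect_equal(unname(lapply(mine, sort)[names(ref)]),
                 unname(lapply(ref, function(x) sort(unique(x)))))
})

test_that("PPI edge lists validate scores and drop self-edges", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("protein_a\tprotein_b\tchannel\tscore",
                 "A\tB\tdatabases\t0.5", "C\tC\texperiments\t0.9"), path)
    expect_warning(ed <- readPpiEdges(path), "self-edge")
    expect_equal(nrow(ed), 1L)
    writeLines(c("protein_a\tprotein_b\tchannel\tscore",
                 "A\tB\tdatabases\t1.5"), path)
    expect_error(readPpiEdges(path), "\\[0, 1\\]")
})

test_that("packaged tumor-specific HR table has the published structure", {
    tab <- loadTumorSpecificHR()
    expect_equal(nrow(tab), 31L)
    expect_equal(anyDuplicated(tab$accession), 0L)
    counts <- table(tab$histotype)
    expect_equal(as.integer(counts[c("SM", "CS", "CG")]), c(4L, 8L, 19L))
    fam <- tab[tab$gene == "FAM83H", ]
    expect_equal(fam$histotype, "SM")
    expect_equal(fam$accession, "A0A494C1T9")
    expect_equal(c(fam$mw_kda, fam$pi), c(149, 6.71))
    tnr <- tab[tab$gene == "TNR", ]
    expect_equal(tnr$histotype, "CG")
    expect_equal(tnr$accession, "Q92752")
})
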