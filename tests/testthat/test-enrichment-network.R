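test_that("hypergeometric upper-tail probability matches exact combinatorics", {
    # N=10, K=4, n=5, k=4: p = C(4,4) C(6,1) / C(10,5) = 6/252
    universe <- paste0("U", 1:10)
    pws <- list(PW = universe[1:4])
    res <- hypergeomORA(universe[c(1:4, 9)], pws, universe)
    expect_equal(res$k, 4)
    expect_equal(res$p_value, 6 / 252)
})

test_that("degenerate overlaps give p = 1", {
    universe <- paste0("U", 1:8)
    pws <- list(A = universe[1:3], B = universe[4:6])
    # k = 0 with K > 0
    res <- hypergeomORA(universe[7:8], pws["A"], universe)
    expect_equal(res$p_value, 1)
    # query = universe: k = K, certain
    res2 <- hypergeomORA(universe, pws, universe)
    expect_equal(res2$p_value, c(1, 1))
    expect_error(hypergeomORA(c("U1", "ZZ"), pws, universe),
                 "outside the universe")
})

test_that("ORA agrees with the exhaustive enumeration oracle for N <= 12", {
    set.seed(13)
    for (i in 1:12) {
        N <- sample(6:12, 1)
        universe <- paste0("U", seq_len(N))
        members <- sample(universe, sample(2:(N - 1), 1))
        n <- sample(2:(N - 2), 1)
        query <- sample(universe, n)
        res <- hypergeomORA(query, list(PW = members), universe)
        oracle <- oracleUpperHyper(universe, members, n, res$k)
        expect_equal(res$p_value, oracle, tolerance = 1e-12)
    }
})

test_that("BH adjustment matches step-up arithmetic and its invariances", {
    expect_equal(bhFDR(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
    expect_equal(bhFDR(0.5), 0.5)
    expect_equal(bhFDR(rep(0.2, 4)), rep(0.2, 4))
    set.seed(3)
    p <- runif(50, 1e-6, 1)
    adj <- bhFDR(p)
    expect_true(all(adj >= p) && all(adj <= 1))
    perm <- sample(50)
    expect_equal(bhFDR(p[perm]), adj[perm])
    expect_error(bhFDR(c(0.5, 0)), "validation")
    expect_error(bhFDR(numeric(0)), "empty")
})

test_that("ORA flags require both raw p and FDR below threshold", {
    universe <- paste0("U", 1:40)
    pws <- list(hit = universe[1:10], miss = universe[31:40])
    res <- hypergeomORA(universe[1:10], pws, universe)
    expect_true(res$significant[res$pathway == "hit"])
    expect_false(res$significant[res$pathway == "miss"])
    expect_equal(res$fdr, bhFDR(res$p_value))
})

test_that("PPI edges filter by channel-specific OR rule with inclusive bounds", {
    ed <- data.frame(
        protein_a = c("A", "A", "B", "B", "C", "D"),
        protein_b = c("B", "B", "C", "C", "D", "E"),
        channel = c("databases", "experiments", "databases", "experiments",
                    "experiments", "databases"),
        score = c(0.35, 0.05, 0.2, 0.1, 0.15, 0.29))
    out <- filterPpiEdges(ed)
    pairs <- unique(paste(out$protein_a, out$protein_b))
    expect_true("A B" %in% pairs)     # databases 0.35 >= 0.3
    expect_false("B C" %in% pairs)    # 0.2 / 0.1 both under
    expect_true("C D" %in% pairs)     # experiments exactly 0.15: inclusive
    expect_false("D E" %in% pairs)    # databases 0.29 < 0.3
})

test_that("edge filtering is idempotent, merges duplicates and is monotone", {
    set.seed(9)
    prots <- paste0("P", 1:12)
    ed <- data.frame(protein_a = sample(prots, 60, TRUE),
                     protein_b = sample(prots, 60, TRUE),
                     channel = sample(c("databases", "experiments"), 60, TRUE),
                     score = round(runif(60), 2))
    ed <- ed[ed$protein_a != ed$protein_b, ]
    f1 <- filterPpiEdges(ed)
    expect_equal(filterPpiEdges(f1), f1)
    # duplicate pairs keep per-channel maxima
    expect_equal(anyDuplicated(paste(f1$protein_a, f1$protein_b, f1$channel)), 0L)
    # raising either threshold never adds pairs
    stricter <- filterPpiEdges(ed, dbThr = 0.6, expThr = 0.4)
    expect_true(all(paste(stricter$protein_a, stricter$protein_b) %in%
                    paste(f1$protein_a, f1$protein_b)))
})

test_that("network annotation carries DEP/specific flags and keeps isolated nodes", {
    m <- rbind(P1 = c(30, 10), P2 = c(5, 5), P3 = c(4, 5))
    colnames(m) <- c("SM", "CS")
    rep_ <- relativeScale(htSE(m))
    deps <- callDEPs(htSE(m), comparisons = list(c("SM", "CS")))
    ed <- data.frame(protein_a = c("P1", "P2"), protein_b = c("P2", "QX"),
                     channel = "databases", score = c(0.9, 0.9))
    expect_warning(
        net <- annotateNetwork(rownames(m), deps, list(CS = "P3"), rep_,
                               filterPpiEdges(ed)),
        "outside the node set")
    expect_equal(net$nodes$is_dep, c(TRUE, FALSE, FALSE))
    expect_equal(net$nodes$specific_histotype, c(NA, NA, "CS"))
    expect_equal(net$nodes$relative_SM, c(100, 100, 80))
    expect_equal(nrow(net$edges), 1L)
    expect_equal(unname(igraph::degree(net$graph)["P3"]), 0)
    # empty edge list -> network of isolated nodes
    net0 <- annotateNetwork(rownames(m), deps, NULL, rep_, NULL)
    expect_equal(igraph::gsize(net0$graph), 0)
    expect_equal(igraph::gorder(net0$graph), 3)
})
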