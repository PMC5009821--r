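triMatrix <- function() {
    matrixFromScores(c("a", "b", "c"), c(0.9, 0.8, 0.3), "simui")
}

test_that("network building filters edges by strict threshold", {
    net <- buildNetwork(triMatrix(), 0.85)
    expect_equal(nrow(networkEdges(net)), 1L)
    expect_setequal(networkNodes(net), c("a", "b", "c"))  # isolated kept
    # threshold below the minimum keeps the complete graph
    full <- buildNetwork(triMatrix(), 0.1)
    expect_equal(nrow(networkEdges(full)), choose(3, 2))
    # ties at the threshold are excluded (strict >)
    tie <- buildNetwork(triMatrix(), 0.8)
    expect_false(any(networkEdges(tie)$score <= 0.8))
    expect_equal(nrow(networkEdges(tie)), 1L)
    # above the maximum: valid empty-edge network with a warning
    expect_warning(empty <- buildNetwork(triMatrix(), 0.95), "no edges")
    expect_equal(nrow(networkEdges(empty)), 0L)
    expect_equal(length(networkNodes(empty)), 3L)
})

test_that("edge sets shrink monotonically as the threshold rises", {
    set.seed(5)
    genes <- paste0("g", 1:8)
    m <- matrixFromScores(genes, runif(choose(8, 2)), "simui")
    edgeKey <- function(net) {
        e <- networkEdges(net)
        paste(pmin(e$gene1, e$gene2), pmax(e$gene1, e$gene2))
    }
    hi <- suppressWarnings(buildNetwork(m, 0.9))  # may have no edges
    lo <- buildNetwork(m, 0.8)
    expect_true(all(edgeKey(hi) %in% edgeKey(lo)))
    for (th in seq(0, 0.9, by = 0.15)) {
        e1 <- edgeKey(suppressWarnings(buildNetwork(m, th + 0.1)))
        e2 <- edgeKey(buildNetwork(m, th))
        expect_true(all(e1 %in% e2))
    }
})

test_that("score histograms conserve the pair count", {
    m <- triMatrix()
    h1 <- scoreHistogram(m, 1)
    expect_equal(sum(h1$count), 3L)
    # uniform scores over ten equal bins: one pair per bin
    genes <- paste0("u", 1:5)
    mu <- matrixFromScores(genes, seq(0.1, 1.0, by = 0.1), "simui")
    h10 <- scoreHistogram(mu, 10)
    expect_equal(h10$count, rep(1L, 10))
    set.seed(8)
    mr <- matrixFromScores(paste0("r", 1:7), runif(21), "simui")
    for (b in c(1, 3, 7))
        expect_equal(sum(scoreHistogram(mr, b)$count), 21L)
    expect_error(scoreHistogram(mr, 0), "bins")
})

test_that("subnetwork selection induces subgraphs with optional neighbors", {
    # path a - b - c
    m <- matrixFromScores(c("a", "b", "c"), c(0.9, 0.1, 0.9), "simui")
    net <- buildNetwork(m, 0.5)
    expect_equal(nrow(networkEdges(net)), 2L)
    # selecting everything is the identity
    all3 <- selectSubnetwork(net, c("a", "b", "c"))
    expect_setequal(networkNodes(all3), networkNodes(net))
    expect_equal(nrow(networkEdges(all3)), nrow(networkEdges(net)))
    # one gene plus neighbors pulls in the adjacent edge
    nb <- selectSubnetwork(net, "a", includeNeighbors = TRUE)
    expect_setequal(networkNodes(nb), c("a", "b"))
    expect_equal(nrow(networkEdges(nb)), 1L)
    # endpoints without the middle: no edges survive induction
    ends <- selectSubnetwork(net, c("a", "c"))
    expect_setequal(networkNodes(ends), c("a", "c"))
    expect_equal(nrow(networkEdges(ends)), 0L)
    # unknown genes are reported, not fatal
    expect_message(selectSubnetwork(net, c("a", "zz")), "zz")
    # empty selection yields an empty network
    none <- selectSubnetwork(net, character())
    expect_equal(length(networkNodes(none)), 0L)
})

test_that("every export format round-trips nodes, edges and scores", {
    set.seed(13)
    genes <- paste0("g", 1:6)
    m <- matrixFromScores(genes, round(runif(15), 4), "simui")
    net <- buildNetwork(m, 0.3)
    for (fmt in c("edge-tsv", "graphml", "cytoscape-json")) {
        path <- tempfile()
        exportNetwork(net, fmt, path)
        back <- importNetwork(path, fmt)
        expect_setequal(networkNodes(back), networkNodes(net))
        eIn <- networkEdges(net); eOut <- networkEdges(back)
        keyIn <- paste(pmin(eIn$gene1, eIn$gene2),
                       pmax(eIn$gene1, eIn$gene2))
        keyOut <- paste(pmin(eOut$gene1, eOut$gene2),
                        pmax(eOut$gene1, eOut$gene2))
        expect_setequal(keyOut, keyIn)
        expect_equal(eOut$score[order(keyOut)], eIn$score[order(keyIn)],
                     tolerance = 1e-6)
        expect_equal(back@threshold, net@threshold)
        expect_equal(back@measure, net@measure)
    }
    expect_error(exportNetwork(net, "dot", tempfile()), "should be one of")
})

test_that("empty-edge networks export as valid node-only files", {
    m <- triMatrix()
    suppressWarnings(net <- buildNetwork(m, 2))
    for (fmt in c("edge-tsv", "graphml", "cytoscape-json")) {
        path <- tempfile()
        exportNetwork(net, fmt, path)
        back <- importNetwork(path, fmt)
        expect_setequal(networkNodes(back), c("a", "b", "c"))
        expect_equal(nrow(networkEdges(back)), 0L)
    }
})

test_that("exports are byte-stable across repeated runs", {
    m <- triMatrix()
    net <- buildNetwork(m, 0.2)
    for (fmt in c("edge-tsv", "graphml", "cytoscape-json")) {
        p1 <- tempfile(); p2 <- tempfile()
        exportNetwork(net, fmt, p1)
        exportNetwork(net, fmt, p2)
        expect_identical(readLines(p1), readLines(p2))
    }
})
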