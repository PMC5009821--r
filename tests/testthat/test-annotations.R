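gafRow <- function(gene, term, qualifier = "enables", evidence = "EXP") {
    paste("SYN", gene, gene, qualifier, term, "SYN_REF:1", evidence, "",
          "F", gene, "", "protein", "taxon:32644", "20260101", "SYN", "", "",
          sep = "\t")
}

test_that("a GAF with one gene on the root yields |G| = 1 and IC(root) = 0", {
    dag <- toyFixture()$dag
    gaf <- tempfile(fileext = ".gaf")
    writeLines(c("!gaf-version: 2.2", gafRow("gX", "R")), gaf)
    corpus <- parseGAF(gaf, dag)
    expect_equal(length(annotatedGenes(corpus)), 1L)
    expect_identical(informationContent(corpus, "R"), 0)
})

test_that("toy annotations propagate to the hand-computed term gene counts", {
    fx <- toyFixture()
    gaf <- tempfile(fileext = ".gaf")
    writeGAF(fx$corpus, gaf)
    corpus <- parseGAF(gaf, fx$dag)
    expect_equal(length(corpus@termGenes[["A"]]), 5L)
    expect_equal(length(corpus@termGenes[["B"]]), 3L)
    expect_setequal(corpus@termGenes[["R"]], annotatedGenes(corpus))
    # round trip: identical propagated sets, gene by gene
    for (g in annotatedGenes(fx$corpus))
        expect_setequal(corpus@propagated[[g]], fx$corpus@propagated[[g]])
})

test_that("evidence exclusion can empty a corpus, which errors", {
    dag <- toyFixture()$dag
    gaf <- tempfile(fileext = ".gaf")
    writeLines(c("!gaf-version: 2.2",
                 gafRow("g1", "A1", evidence = "IEA"),
                 gafRow("g2", "B1", evidence = "IEA")), gaf)
    expect_error(parseGAF(gaf, dag, evidenceExclude = "IEA"),
                 "no usable annotation rows")
    # without the exclusion the same file parses
    expect_equal(length(annotatedGenes(parseGAF(gaf, dag))), 2L)
})

test_that("NOT-qualified rows and unknown terms are dropped", {
    dag <- toyFixture()$dag
    gaf <- tempfile(fileext = ".gaf")
    writeLines(c("!gaf-version: 2.2",
                 gafRow("g1", "A1"),
                 gafRow("g1", "B1", qualifier = "NOT|enables"),
                 gafRow("g2", "GO:9999999")), gaf)
    expect_message(corpus <- parseGAF(gaf, dag), "dropped 1")
    expect_equal(annotatedGenes(corpus), "g1")
    expect_setequal(corpus@propagated[["g1"]], c("A1", "A", "R"))
})

test_that("a column-count violation is a parse error naming the row", {
    dag <- toyFixture()$dag
    gaf <- tempfile(fileext = ".gaf")
    writeLines(c("!gaf-version: 2.2", "only\tfour\tcolumns\there"), gaf)
    expect_error(parseGAF(gaf, dag), "row 1")
})

test_that("the two-column TSV alternative parses to the same corpus", {
    fx <- toyFixture()
    tsv <- tempfile(fileext = ".tsv")
    rows <- unlist(lapply(names(fx$corpus@direct), function(g)
        paste(g, fx$corpus@direct[[g]], sep = "\t")))
    writeLines(rows, tsv)
    corpus <- parseAnnotationsTSV(tsv, fx$dag)
    for (g in annotatedGenes(fx$corpus))
        expect_setequal(corpus@propagated[[g]], fx$corpus@propagated[[g]])
})

test_that("IC values match hand computation in natural-log units", {
    corpus <- toyFixture()$corpus
    expect_equal(informationContent(corpus, "A"), -log(5 / 8),
                 tolerance = 1e-12)
    expect_equal4(informationContent(corpus, "A"), 0.4700)
    expect_identical(informationContent(corpus, "R"), 0)
    expect_equal(informationContent(corpus, "A2"), log(8), tolerance = 1e-12)
    expect_equal4(informationContent(corpus, "A2"), 2.0794)
})

test_that("IC of a term with no annotations is an explicit error", {
    fx <- toyFixture()
    corpus <- annotationCorpus(fx$dag, list(x = "A1"))
    expect_error(informationContent(corpus, "B1"), "undefined")
})

test_that("the most informative common ancestor matches hand enumeration", {
    fx <- toyFixture()
    expect_equal(mica(fx$corpus, fx$dag, "A1", "A2"), "A")
    expect_equal(mica(fx$corpus, fx$dag, "A1", "B1"), "R")
    for (t in termIds(fx$dag))
        expect_equal(mica(fx$corpus, fx$dag, t, t), t)
})

test_that("propagation obeys the true path rule and MICA maximizes IC", {
    for (seed in 1:5) {
        adj <- randomParentAdjacency(12, maxParents = 3, seed = seed)
        dag <- dagFromAdjacency(adj)
        direct <- randomDirectAnnotations(adj$ids, nGenes = 8, perGene = 2,
                                          seed = seed + 100)
        corpus <- annotationCorpus(dag, direct)
        # |G_parent| >= |G_child| for every edge among annotated terms
        for (t in names(corpus@termGenes)) {
            for (p in dag@parents[[t]])
                expect_gte(length(corpus@termGenes[[p]]),
                           length(corpus@termGenes[[t]]))
        }
        # child IC >= parent IC along every annotated edge
        for (t in names(corpus@ic)) {
            for (p in dag@parents[[t]])
                expect_gte(corpus@ic[[t]], corpus@ic[[p]] - 1e-12)
        }
        annot <- names(corpus@ic)
        pick <- sample(annot, min(4, length(annot)))
        for (a in pick) for (b in pick) {
            m <- mica(corpus, dag, a, b)
            ca <- oracleCommonAncestors(adj$parentsOf, a, b)
            ca <- intersect(ca, annot)
            expect_true(all(corpus@ic[[m]] >= corpus@ic[ca] - 1e-12))
        }
    }
})
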