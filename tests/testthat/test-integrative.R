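fx <- toyFixture()

test_that("rank matrices rank descending with mean ties and normalize to [0,1]", {
    g3 <- c("a", "b", "c")
    m <- matrixFromScores(g3, c(0.9, 0.5, 0.1), "m1")
    rm <- buildRankMatrix(list(m))
    expect_equal(unname(rm@ranks[, 1]), c(1, 2, 3))
    expect_equal(unname(rm@rprime[, 1]), c(1, 0.5, 0))
    # ties share the mean of their positions
    mt <- matrixFromScores(g3, c(0.7, 0.7, 0.2), "m1")
    rt <- buildRankMatrix(list(mt))
    expect_equal(unname(rt@ranks[, 1]), c(1.5, 1.5, 3))
    # identical matrices give identical columns
    r2 <- buildRankMatrix(list(m1 = m, m2 = m))
    expect_equal(r2@ranks[, "m1"], r2@ranks[, "m2"])
    # mismatched gene sets cannot be aligned
    other <- matrixFromScores(c("a", "b", "x"), c(1, 1, 1), "m2")
    expect_error(buildRankMatrix(list(m, other)), "different gene sets")
})

test_that("rank normalization is invariant to monotone transforms", {
    genes <- paste0("g", 1:6)
    m <- geneSimMatrix(fx$corpus, genes, "simui")
    warped <- m
    warped@scores <- tanh(3 * m@scores)  # strictly monotone warp
    expect_equal(buildRankMatrix(list(m))@rprime,
                 buildRankMatrix(list(warped))@rprime)
})

test_that("seed selection keeps concordant measures and excludes outliers", {
    genes <- paste0("p", 1:5)  # 10 pairs
    base <- seq(0.9, 0.1, length.out = 9)
    # pair 1 is top-ranked by m1/m2 but bottom-ranked by m3
    m1 <- matrixFromScores(genes, c(1.0, base), "m1")
    m3 <- matrixFromScores(genes, c(0.05, base), "m3")
    rm <- buildRankMatrix(list(m1 = m1, m2 = m1, m3 = m3))
    sel <- selectSeedMeasures(rm, delta = 0.2)
    i <- which(rm@ranks[, "m1"] == 1)  # the disputed pair
    expect_true(all(sel@selected[i, c("m1", "m2")]))
    expect_false(sel@selected[i, "m3"])
    # full agreement selects every measure
    rmAgree <- buildRankMatrix(list(m1 = m1, m2 = m1))
    expect_true(all(selectSeedMeasures(rmAgree, 0.2)@selected))
    # single-measure input falls back to that measure everywhere
    rmSingle <- buildRankMatrix(list(m1 = m1))
    expect_true(all(selectSeedMeasures(rmSingle, 0.2)@selected))
    expect_error(selectSeedMeasures(rm, 0), "delta")
})

test_that("pair integration is the weighted mean over selected measures", {
    genes <- c("a", "b", "c")
    mk <- function(scores, nm) matrixFromScores(genes, scores, nm)
    rm <- buildRankMatrix(list(m1 = mk(c(0.9, 0.5, 0.1), "m1"),
                               m2 = mk(c(0.1, 0.5, 0.9), "m2")))
    allSel <- new("SeedSelection",
                  selected = matrix(TRUE, 3, 2,
                                    dimnames = list(NULL, c("m1", "m2"))),
                  delta = 1)
    model <- function(w) new("IntegrationModel",
                             weights = c(m1 = w[1], m2 = w[2]), delta = 1,
                             seed = 1L, iterations = 0L, objective = 0)
    # equal weights: arithmetic mean of r' = (1, 0) -> 0.5
    expect_equal(integratePair(model(c(1, 1)), rm, allSel, 1L), 0.5)
    # weights 3:1 on r' = (1, 0) -> 0.75
    expect_equal(integratePair(model(c(3, 1)), rm, allSel, 1L), 0.75)
    # one selected measure: score equals that measure's r'
    oneSel <- allSel
    oneSel@selected[, 2] <- FALSE
    expect_equal(unname(integratePair(model(c(1, 1)), rm, oneSel, 1L)),
                 unname(rm@rprime[1, "m1"]))
    # all-zero selected weights are a degenerate model
    expect_error(integratePair(model(c(0, 1)), rm, oneSel, 1L), "degenerate")
})

test_that("group separation reproduces the printed worked example", {
    genes <- c("a", "b", "c", "d")
    groups <- ecGroups(c(a = "EC1", b = "EC1", c = "EC2", d = "EC2"))
    # pair order a-b, a-c, b-c, a-d, b-d, c-d
    m <- matrixFromScores(genes, c(0.9, 0.3, 0.2, 0.4, 0.1, 0.8), "intego2")
    expect_equal(groupSeparation(m, groups), 0.85 - 0.25)
    # maximal separation and no separation
    mMax <- matrixFromScores(genes, c(1, 0, 0, 0, 0, 1), "intego2")
    expect_equal(groupSeparation(mMax, groups), 1)
    mFlat <- matrixFromScores(genes, rep(0.4, 6), "intego2")
    expect_equal(groupSeparation(mFlat, groups), 0)
})

test_that("the separation objective is zero when every pair scores alike", {
    genes <- c("a", "b", "c", "d")
    groups <- ecGroups(c(a = "EC1", b = "EC1", c = "EC2", d = "EC2"))
    mFlat <- matrixFromScores(genes, rep(0.4, 6), "m1")
    expect_equal(separationObjective(c(m1 = 1), 0.2, list(m1 = mFlat),
                                     groups), 0)
    # groups must all have >= 2 genes
    expect_error(ecGroups(c(a = "EC1", b = "EC1", c = "EC2")),
                 "at least two genes")
})

test_that("weight training is seeded, improving, and degenerate-safe", {
    fe <- ecGroupedCorpus(fixtureSpec(nGenes = 12, nEcGroups = 3,
                                      coherence = 0.9, seed = 21))
    genes <- names(fe$groups@groups)
    mats <- list(simui = geneSimMatrix(fe$corpus, genes, "simui"),
                 simgic = geneSimMatrix(fe$corpus, genes, "simgic"))
    m1 <- trainWeights(mats, fe$groups, iterations = 300, seed = 9)
    m2 <- trainWeights(mats, fe$groups, iterations = 300, seed = 9)
    expect_equal(modelWeights(m1), modelWeights(m2))
    expect_equal(sum(modelWeights(m1)), 1)
    uniformObj <- separationObjective(
        c(simui = 0.5, simgic = 0.5), 0.2, mats, fe$groups)
    expect_gte(m1@objective, uniformObj - 1e-12)
    # single measure: the simplex is a point
    mOne <- trainWeights(mats["simui"], fe$groups, iterations = 10, seed = 1)
    expect_equal(modelWeights(mOne), c(simui = 1))
    # duplicated measures cannot change the objective
    matsDup <- list(a = mats$simui, b = mats$simui)
    objDup <- separationObjective(c(a = 0.8, b = 0.2), 0.2, matsDup,
                                  fe$groups)
    objSingle <- separationObjective(c(a = 1), 0.2, matsDup["a"], fe$groups)
    expect_equal(objDup, objSingle)
    expect_error(trainWeights(mats, fe$groups, iterations = 0, seed = 1),
                 "budget")
})

test_that("training recovers an informative measure over pure noise", {
    fe <- ecGroupedCorpus(fixtureSpec(nGenes = 16, nEcGroups = 4,
                                      coherence = 0.95, seed = 31))
    genes <- names(fe$groups@groups)
    informative <- geneSimMatrix(fe$corpus, genes, "simui")
    set.seed(77)
    noise <- matrixFromScores(sort(genes),
                              runif(choose(length(genes), 2)), "noise")
    model <- trainWeights(list(informative = informative, noise = noise),
                          fe$groups, iterations = 1000, seed = 3)
    expect_gt(modelWeights(model)[["informative"]],
              modelWeights(model)[["noise"]])
})

test_that("the integrative matrix inherits symmetry, bounds and order independence", {
    genes <- paste0("g", 1:7)
    m <- intego2Matrix(fx$corpus, genes, fx$dag)
    s <- simScores(m)
    expect_equal(s, t(s))
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(simMeasure(m), "intego2")
    mPerm <- intego2Matrix(fx$corpus, rev(genes), fx$dag)
    expect_equal(simScores(mPerm)[genes, genes], s[genes, genes])
    # dropping a seed measure breaks no invariant
    mDrop <- intego2Matrix(fx$corpus, genes, fx$dag,
                           measures = c("simui", "simgic", "wang"))
    sD <- simScores(mDrop)
    expect_equal(sD, t(sD))
    expect_true(all(sD >= 0 & sD <= 1))
    # unavailable candidates are dropped with a warning, not an error
    expect_warning(
        mW <- intego2Matrix(fx$corpus, genes, fx$dag,
                            measures = c("simui", "hrss_missing")),
        "unavailable")
    expect_equal(simMeasure(mW), "intego2")
})

test_that("integration models serialize to JSON and back", {
    model <- new("IntegrationModel",
                 weights = c(simui = 0.25, wang = 0.75), delta = 0.3,
                 seed = 11L, iterations = 500L, objective = 0.421)
    path <- tempfile(fileext = ".json")
    writeIntegrationModel(model, path)
    back <- readIntegrationModel(path)
    expect_equal(modelWeights(back), modelWeights(model))
    expect_equal(back@delta, model@delta)
    expect_equal(back@seed, model@seed)
    expect_equal(back@objective, model@objective)
})
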