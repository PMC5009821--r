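# Independent brute-force oracles used to check the package's dynamic
# programming and closure computations. Everything here works from a plain
# parent adjacency list by exhaustive path enumeration / set arithmetic,
# never through the package's precomputed structures.

# All upward paths from `term` (each path a vector of node ids starting at
# term, ending wherever it stops extending).
allUpwardPaths <- function(parentsOf, term) {
    ps <- parentsOf[[term]]
    if (!length(ps)) return(list(term))
    out <- list()
    for (p in ps) {
        for (path in allUpwardPaths(parentsOf, p))
            out <- c(out, list(c(term, path)))
    }
    out
}

# Ancestors by exhaustive path enumeration.
oracleAncestors <- function(parentsOf, term, includeSelf = FALSE) {
    nodes <- unique(unlist(allUpwardPaths(parentsOf, term)))
    if (includeSelf) nodes else setdiff(nodes, term)
}

oracleCommonAncestors <- function(parentsOf, ta, tb) {
    intersect(oracleAncestors(parentsOf, ta, TRUE),
              oracleAncestors(parentsOf, tb, TRUE))
}

# Max product of edge weights over all paths from term up to ancestor.
# relOf[[child]] holds the relation of each parent edge, parallel to
# parentsOf[[child]].
oracleSValue <- function(parentsOf, relOf, term, anc, w) {
    if (term == anc) return(1)
    best <- -Inf
    ps <- parentsOf[[term]]
    for (k in seq_along(ps)) {
        sub <- oracleSValue(parentsOf, relOf, ps[[k]], anc, w)
        if (is.finite(sub))
            best <- max(best, w[[relOf[[term]][[k]]]] * sub)
    }
    best
}

# Propagated annotation sets and IC from direct annotations, by brute
# closure.
oraclePropagate <- function(parentsOf, direct) {
    lapply(direct, function(ts)
        unique(unlist(lapply(ts, oracleAncestors, parentsOf = parentsOf,
                             includeSelf = TRUE))))
}

oracleIC <- function(parentsOf, direct, term) {
    prop <- oraclePropagate(parentsOf, direct)
    n <- sum(vapply(prop, function(p) term %in% p, logical(1)))
    -log(n / length(prop))
}

oracleMICA <- function(parentsOf, direct, ta, tb) {
    ca <- oracleCommonAncestors(parentsOf, ta, tb)
    ic <- vapply(ca, oracleIC, numeric(1),
                 parentsOf = parentsOf, direct = direct)
    sort(ca[ic == max(ic)])[[1L]]
}

# The TOY1 fixture restated independently of the package, as plain lists.
toyParents <- list(R = character(), A = "R", B = "R", A1 = "A", A2 = "A",
                   B1 = "B", C = c("A", "B"))
toyRels <- lapply(toyParents, function(p) rep("is_a", length(p)))
toyDirect <- list(g1 = "A1", g2 = "A1", g3 = "A2", g4 = "B1", g5 = "C",
                  g6 = "B", g7 = "A", g8 = "R")

# Random DAG in plain-adjacency form mirroring the generator's scheme
# (term i parents only earlier terms), for oracle-vs-implementation runs.
randomParentAdjacency <- function(n, maxParents, seed) {
    set.seed(seed)
    ids <- sprintf("T%03d", seq_len(n))
    parentsOf <- list(); relOf <- list()
    parentsOf[[ids[[1L]]]] <- character()
    relOf[[ids[[1L]]]] <- character()
    for (i in seq_len(n)[-1L]) {
        k <- sample.int(min(maxParents, i - 1L), 1L)
        parentsOf[[ids[[i]]]] <- ids[sample.int(i - 1L, k)]
        relOf[[ids[[i]]]] <- sample(c("is_a", "part_of"), k, replace = TRUE)
    }
    list(ids = ids, parentsOf = parentsOf, relOf = relOf)
}

# Build the package DAG from a plain adjacency (shared input for both
# routes of a dual-route check).
dagFromAdjacency <- function(adj, namespace = "molecular_function") {
    goSimNet:::newOntologyDAG(adj$ids, paste("t", adj$ids), adj$parentsOf,
                              adj$relOf, namespace)
}

# Random direct annotations over an id set.
randomDirectAnnotations <- function(ids, nGenes, perGene, seed) {
    set.seed(seed)
    direct <- lapply(seq_len(nGenes), function(i)
        sample(ids, min(perGene, length(ids))))
    names(direct) <- sprintf("g%02d", seq_len(nGenes))
    direct
}

# Similarity matrix built directly from a pair-score vector, bypassing the
# measure pipeline (for rank/selection/network unit tests).
matrixFromScores <- function(genes, scores, measure = "test",
                             normalized = TRUE, diagValue = 1) {
    n <- length(genes)
    s <- matrix(0, n, n, dimnames = list(genes, genes))
    s[upper.tri(s)] <- scores
    s <- s + t(s)
    diag(s) <- diagValue
    new("GeneSimilarityMatrix", measure = measure, genes = genes,
        scores = s, normalized = normalized, skipped = character())
}

# Agreement to four printed decimal places (absolute, not relative).
expect_equal4 <- function(object, expected) {
    testthat::expect_lt(abs(object - expected), 5e-5)
}
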