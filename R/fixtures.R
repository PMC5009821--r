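#' Fixture generator specification
#'
#' Bundles every knob of the synthetic-fixture generators; the same spec
#' and seed always reproduce byte-identical fixtures.
#'
#' @param nTerms ontology size for [randomOntology()]
#' @param maxParents maximum parents per non-root term
#' @param nGenes total genes in a generated corpus
#' @param annotationsPerGene direct annotations per gene
#' @param nEcGroups number of EC groups for [ecGroupedCorpus()]
#' @param coherence probability a group member draws each annotation from
#'   its own group's term pool (1 = fully coherent groups, 0 = labels carry
#'   no signal)
#' @param seed RNG seed
#' @return a [FixtureSpec-class]
#' @export
fixtureSpec <- function(nTerms = 30L, maxParents = 3L, nGenes = 20L,
                        annotationsPerGene = 3L, nEcGroups = 4L,
                        coherence = 0.9, seed = 1L) {
    new("FixtureSpec",
        nTerms = as.integer(nTerms), maxParents = as.integer(maxParents),
        nGenes = as.integer(nGenes),
        annotationsPerGene = as.integer(annotationsPerGene),
        nEcGroups = as.integer(nEcGroups),
        coherence = as.numeric(coherence), seed = as.integer(seed))
}

#' Serialize a fixture spec as JSON
#'
#' @param spec a [FixtureSpec-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeFixtureSpec <- function(spec, path) {
    jsonlite::write_json(
        list(nTerms = spec@nTerms, maxParents = spec@maxParents,
             nGenes = spec@nGenes,
             annotationsPerGene = spec@annotationsPerGene,
             nEcGroups = spec@nEcGroups, coherence = spec@coherence,
             seed = spec@seed),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' Read a fixture spec from JSON
#'
#' @param path JSON path written by [writeFixtureSpec()]
#' @return a [FixtureSpec-class]
#' @export
readFixtureSpec <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    do.call(fixtureSpec, x)
}

#' The TOY1 hand-checkable fixture
#'
#' A frozen seven-term, two-level ontology with one multi-parent term and
#' an eight-gene corpus whose propagated counts and IC values are small
#' enough to verify by hand: terms R (root); A, B is_a R; A1, A2 is_a A;
#' B1 is_a B; C is_a both A and B. Direct annotations: g1, g2 -> A1,
#' g3 -> A2, g4 -> B1, g5 -> C, g6 -> B, g7 -> A, g8 -> R. After
#' propagation |G_A| = 5, |G_B| = 3, |G_R| = 8, so for instance
#' IC(A) = -ln(5/8) and IC(B) = -ln(3/8).
#'
#' @return list with components \code{dag} ([OntologyDAG-class]) and
#'   \code{corpus} ([AnnotationCorpus-class])
#' @examples
#' fx <- toyFixture()
#' informationContent(fx$corpus, "A")
#' @export
toyFixture <- function() {
    ids <- c("R", "A", "B", "A1", "A2", "B1", "C")
    parents <- list(R = character(), A = "R", B = "R", A1 = "A", A2 = "A",
                    B1 = "B", C = c("A", "B"))
    rels <- lapply(parents, function(p) rep("is_a", length(p)))
    dag <- newOntologyDAG(ids, paste("term", ids), parents, rels,
                          "molecular_function")
    direct <- list(g1 = "A1", g2 = "A1", g3 = "A2", g4 = "B1", g5 = "C",
                   g6 = "B", g7 = "A", g8 = "R")
    list(dag = dag, corpus = annotationCorpus(dag, direct))
}

#' Random seeded ontology DAG
#'
#' Generates an acyclic, single-rooted DAG: term 1 is the root and each
#' later term draws 1 to \code{maxParents} parents uniformly from the
#' terms before it (acyclicity by construction). About one edge in five is
#' \code{part_of}, the rest \code{is_a}.
#'
#' @param spec a [FixtureSpec-class] (uses nTerms, maxParents, seed)
#' @return an [OntologyDAG-class]
#' @export
randomOntology <- function(spec) {
    validObject(spec)
    n <- spec@nTerms
    ids <- sprintf("T%03d", seq_len(n))
    withLocalSeed(spec@seed, {
        parents <- list(); rels <- list()
        parents[[ids[[1L]]]] <- character()
        rels[[ids[[1L]]]] <- character()
        for (i in seq_len(n)[-1L]) {
            k <- sample.int(min(spec@maxParents, i - 1L), 1L)
            ps <- ids[sample.int(i - 1L, k)]
            parents[[ids[[i]]]] <- ps
            rels[[ids[[i]]]] <- sample(c("is_a", "part_of"), k,
                                       replace = TRUE, prob = c(0.8, 0.2))
        }
        newOntologyDAG(ids, paste("synthetic term", ids), parents, rels,
                       "molecular_function")
    })
}

#' Random annotated corpus on a random ontology
#'
#' Convenience generator for property tests: draws
#' \code{annotationsPerGene} direct annotations per gene uniformly from
#' the ontology's terms.
#'
#' @param spec a [FixtureSpec-class]
#' @param dag optional pre-built [OntologyDAG-class]; defaults to
#'   \code{randomOntology(spec)}
#' @return list with \code{dag} and \code{corpus}
#' @export
randomCorpus <- function(spec, dag = NULL) {
    validObject(spec)
    if (is.null(dag)) dag <- randomOntology(spec)
    withLocalSeed(spec@seed + 1L, {
        genes <- sprintf("g%03d", seq_len(spec@nGenes))
        direct <- lapply(genes, function(g)
            sample(dag@termIds,
                   min(spec@annotationsPerGene, length(dag@termIds))))
        names(direct) <- genes
        list(dag = dag, corpus = annotationCorpus(dag, direct))
    })
}

#' EC-grouped synthetic corpus
#'
#' Emulates an EC-labelled training set with controllable functional
#' coherence. The backing ontology has a root, one branch term per EC
#' group, and a disjoint pool of leaf terms under each branch. Genes are
#' split evenly over the groups; each gene draws
#' \code{annotationsPerGene} distinct leaf terms, each taken from its own
#' group's pool with probability \code{coherence} and uniformly from all
#' pools otherwise. At coherence 1 within-group pairs always share their
#' branch term and between-group pairs share only the root, so group
#' labels are fully recoverable from similarity; at coherence 0 the
#' labels carry no signal.
#'
#' @param spec a [FixtureSpec-class] with \code{nEcGroups >= 2} and at
#'   least two genes per group
#' @return list with \code{dag}, \code{corpus} and \code{groups}
#'   (an [ECGroupedGenes-class])
#' @examples
#' fx <- ecGroupedCorpus(fixtureSpec(nGenes = 12, nEcGroups = 3, seed = 2))
#' fx$groups
#' @export
ecGroupedCorpus <- function(spec) {
    validObject(spec)
    k <- spec@nEcGroups
    if (k < 2L)
        stop("EC corpora need at least two groups", call. = FALSE)
    if (spec@nGenes < 2L * k)
        stop("EC corpora need at least two genes per group", call. = FALSE)
    poolSize <- max(3L * spec@annotationsPerGene, 4L)

    branch <- sprintf("EC%02d", seq_len(k))
    ids <- "R"
    parents <- list(R = character())
    for (b in branch) {
        ids <- c(ids, b)
        parents[[b]] <- "R"
        pool <- sprintf("%s_T%02d", b, seq_len(poolSize))
        ids <- c(ids, pool)
        for (t in pool) parents[[t]] <- b
    }
    rels <- lapply(parents, function(p) rep("is_a", length(p)))
    dag <- newOntologyDAG(ids, paste("synthetic term", ids), parents, rels,
                          "molecular_function")

    pools <- lapply(branch, function(b)
        sprintf("%s_T%02d", b, seq_len(poolSize)))
    allPool <- unlist(pools)

    genes <- sprintf("g%03d", seq_len(spec@nGenes))
    label <- branch[rep_len(seq_len(k), spec@nGenes)]
    withLocalSeed(spec@seed, {
        direct <- vector("list", spec@nGenes)
        names(direct) <- genes
        for (i in seq_along(genes)) {
            own <- pools[[match(label[[i]], branch)]]
            picked <- character()
            while (length(picked) < spec@annotationsPerGene) {
                src <- if (stats::runif(1L) < spec@coherence) own
                       else allPool
                cand <- setdiff(src, picked)
                if (!length(cand)) cand <- setdiff(allPool, picked)
                picked <- c(picked, sample(cand, 1L))
            }
            direct[[i]] <- picked
        }
        corpus <- annotationCorpus(dag, direct)
        list(dag = dag, corpus = corpus,
             groups = ecGroups(structure(label, names = genes)))
    })
}
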