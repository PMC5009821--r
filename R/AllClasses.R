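#' @import methods
NULL

#' Gene Ontology DAG
#'
#' A parsed, single-namespace slice of the Gene Ontology (or a synthetic
#' ontology in the same shape): non-obsolete terms connected by \code{is_a}
#' and \code{part_of} edges, rooted at the namespace root. Ancestor sets are
#' precomputed at construction so that every downstream similarity measure
#' can treat ancestor lookup as O(1).
#'
#' @slot namespace single namespace the DAG was loaded for, one of
#'   \code{molecular_function}, \code{biological_process},
#'   \code{cellular_component} (synthetic ontologies may use any label).
#' @slot termIds character vector of term accessions.
#' @slot termNames term id -> human-readable name.
#' @slot parents term id -> character vector of direct parent ids.
#' @slot parentRels term id -> relation of each parent edge
#'   (\code{is_a} or \code{part_of}), parallel to \code{parents}.
#' @slot children term id -> character vector of direct child ids.
#' @slot root the namespace root (unique term with no parents).
#' @slot ancestorSets term id -> all proper ancestors (transitive closure
#'   over is_a and part_of; excludes the term itself).
#' @slot topoOrder term ids sorted parents-before-children.
#' @slot altIds secondary accession -> canonical accession.
#'
#' @seealso [parseOBO()], [ancestors()], [commonAncestors()], [leavesBelow()]
#' @export
setClass("OntologyDAG",
    representation(
        namespace    = "character",
        termIds      = "character",
        termNames    = "character",
        parents      = "list",
        parentRels   = "list",
        children     = "list",
        root         = "character",
        ancestorSets = "list",
        topoOrder    = "character",
        altIds       = "character"
    )
)

setValidity("OntologyDAG", function(object) {
    msg <- character()
    ids <- object@termIds
    if (anyDuplicated(ids))
        msg <- c(msg, "term ids must be unique")
    if (length(object@root) != 1L || !(object@root %in% ids))
        msg <- c(msg, "DAG must have exactly one root present among terms")
    if (length(object@topoOrder) != length(ids))
        msg <- c(msg, "topological order must cover every term (graph must be acyclic)")
    nonroot <- setdiff(ids, object@root)
    ok <- vapply(nonroot, function(t) object@root %in% object@ancestorSets[[t]],
                 logical(1))
    if (length(ok) && !all(ok))
        msg <- c(msg, "every non-root term must reach the namespace root")
    if (length(msg)) msg else TRUE
})

#' Annotation corpus with true-path propagation and information content
#'
#' Direct and propagated gene-to-term annotation maps for one GO namespace,
#' the inverse term-to-gene map over propagated annotations, and the
#' information-content table IC(t) = -ln(|G_t| / |G|), where G is the set of
#' annotated genes and G_t the genes annotated (after propagation) to t.
#'
#' @slot direct gene -> character vector of directly annotated term ids.
#' @slot propagated gene -> direct terms plus all their ancestors
#'   (true path rule).
#' @slot termGenes term id -> genes annotated after propagation.
#' @slot genes all annotated gene ids (G).
#' @slot ic term id -> information content in nats; defined only for terms
#'   with at least one propagated annotation; IC(root) is exactly 0.
#' @slot namespace namespace of the backing DAG.
#' @slot root the backing DAG's root term.
#'
#' @seealso [parseGAF()], [annotationCorpus()], [informationContent()], [mica()]
#' @export
setClass("AnnotationCorpus",
    representation(
        direct     = "list",
        propagated = "list",
        termGenes  = "list",
        genes      = "character",
        ic         = "numeric",
        namespace  = "character",
        root       = "character"
    )
)

setValidity("AnnotationCorpus", function(object) {
    msg <- character()
    if (!length(object@genes))
        msg <- c(msg, "corpus must contain at least one annotated gene")
    if (object@root %in% names(object@ic) &&
        abs(object@ic[[object@root]]) > 0)
        msg <- c(msg, "IC(root) must be exactly 0")
    nprop <- lengths(object@propagated)
    if (length(nprop) && any(nprop == 0L))
        msg <- c(msg, "every gene must have at least one propagated term")
    if (length(msg)) msg else TRUE
})

#' Symmetric gene-by-gene similarity matrix for one measure
#'
#' @slot measure registry name of the measure that produced the scores
#'   (resnik, schlicker, wang, hrss, simui, simgic, to, intego2).
#' @slot genes gene ids, in matrix order.
#' @slot scores symmetric numeric matrix with \code{genes} as dimnames.
#' @slot normalized TRUE when scores are guaranteed to lie in [0, 1]
#'   (term overlap, for instance, is a raw count and is not).
#' @slot skipped input genes dropped for lack of GO annotation.
#'
#' @seealso [geneSimMatrix()], [simScores()]
#' @export
setClass("GeneSimilarityMatrix",
    representation(
        measure    = "character",
        genes      = "character",
        scores     = "matrix",
        normalized = "logical",
        skipped    = "character"
    )
)

setValidity("GeneSimilarityMatrix", function(object) {
    msg <- character()
    s <- object@scores
    n <- length(object@genes)
    if (!is.numeric(s) || nrow(s) != n || ncol(s) != n)
        msg <- c(msg, "scores must be an n x n numeric matrix over the genes")
    else {
        if (!identical(rownames(s), object@genes) ||
            !identical(colnames(s), object@genes))
            msg <- c(msg, "scores dimnames must equal the gene vector")
        if (n && !isTRUE(all.equal(s, t(s), tolerance = 1e-10)))
            msg <- c(msg, "score matrix must be symmetric")
    }
    if (length(msg)) msg else TRUE
})

#' Per-measure rank matrix over gene pairs
#'
#' For each measure, every unordered gene pair is ranked by descending raw
#' similarity (rank 1 = most similar; ties get the mean of the tied rank
#' positions), and ranks are mapped to normalized scores
#' r' = 1 - (rank - 1) / (N - 1) in [0, 1].
#'
#' @slot pairs data.frame with columns gene1, gene2 (one row per
#'   unordered pair).
#' @slot measures measure names, one per column of the rank tables.
#' @slot ranks N-pairs x N-measures matrix of (possibly fractional) ranks.
#' @slot rprime matching matrix of normalized rank scores in [0, 1].
#'
#' @seealso [buildRankMatrix()], [selectSeedMeasures()]
#' @export
setClass("RankMatrix",
    representation(
        pairs    = "data.frame",
        measures = "character",
        ranks    = "matrix",
        rprime   = "matrix"
    )
)

setValidity("RankMatrix", function(object) {
    msg <- character()
    np <- nrow(object@pairs)
    nm <- length(object@measures)
    if (nrow(object@ranks) != np || ncol(object@ranks) != nm)
        msg <- c(msg, "rank matrix dimensions must be n_pairs x n_measures")
    if (np > 0 && nm > 0) {
        if (any(object@rprime < -1e-12 | object@rprime > 1 + 1e-12))
            msg <- c(msg, "normalized rank scores must lie in [0, 1]")
        sums <- colSums(object@ranks)
        if (any(abs(sums - np * (np + 1) / 2) > 1e-8))
            msg <- c(msg, "each measure's ranks must be a permutation-with-ties of 1..N")
    }
    if (length(msg)) msg else TRUE
})

#' Seed-measure selection per gene pair
#'
#' For each gene pair, the subset of candidate measures whose rank of that
#' pair falls within a window of width delta * N around the pair's median
#' rank; always non-empty (falls back to the measure nearest the median).
#'
#' @slot selected logical N-pairs x N-measures matrix; TRUE = selected.
#' @slot delta the window parameter used, in (0, 1].
#'
#' @seealso [selectSeedMeasures()], [integratePair()]
#' @export
setClass("SeedSelection",
    representation(selected = "matrix", delta = "numeric")
)

setValidity("SeedSelection", function(object) {
    msg <- character()
    if (!is.logical(object@selected))
        msg <- c(msg, "selection must be a logical matrix")
    else if (nrow(object@selected) > 0 && any(rowSums(object@selected) == 0))
        msg <- c(msg, "every pair must have at least one selected measure")
    if (object@delta <= 0 || object@delta > 1)
        msg <- c(msg, "delta must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Trained parameters of the integrative measure
#'
#' Non-negative per-measure weights (normalized to sum 1) of the additive
#' integration model, the grouping window delta they were trained with, and
#' reproducibility metadata of the simulated-annealing search.
#'
#' @slot weights measure -> weight (>= 0, sum 1; at least one positive).
#' @slot delta grouping window in (0, 1], fixed at training time and reused
#'   at scoring time.
#' @slot seed RNG seed of the training run.
#' @slot iterations annealing iteration budget.
#' @slot objective best EC-group separation objective reached.
#'
#' @seealso [trainWeights()], [integratePair()], [writeIntegrationModel()]
#' @export
setClass("IntegrationModel",
    representation(
        weights    = "numeric",
        delta      = "numeric",
        seed       = "integer",
        iterations = "integer",
        objective  = "numeric"
    )
)

setValidity("IntegrationModel", function(object) {
    msg <- character()
    if (is.null(names(object@weights)) || any(!nzchar(names(object@weights))))
        msg <- c(msg, "weights must be named by measure")
    if (any(object@weights < 0))
        msg <- c(msg, "weights must be non-negative")
    if (!any(object@weights > 0))
        msg <- c(msg, "at least one weight must be positive")
    if (object@delta <= 0 || object@delta > 1)
        msg <- c(msg, "delta must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Enzyme Commission grouped training genes
#'
#' Gene -> EC-group labels used as functional ground truth when training the
#' integration weights: genes sharing an EC class are expected to be more
#' functionally similar than genes from distinct classes.
#'
#' @slot groups named character vector, gene id -> group label.
#'
#' @seealso [ecGroups()], [separationObjective()], [trainWeights()]
#' @export
setClass("ECGroupedGenes", representation(groups = "character"))

setValidity("ECGroupedGenes", function(object) {
    msg <- character()
    g <- object@groups
    if (is.null(names(g)) || any(!nzchar(names(g))))
        msg <- c(msg, "groups must be named by gene id")
    if (anyDuplicated(names(g)))
        msg <- c(msg, "each gene may carry one group label")
    tab <- table(g)
    if (length(tab) < 2L)
        msg <- c(msg, "at least two EC groups are required")
    if (length(tab) && any(tab < 2L))
        msg <- c(msg, "every EC group needs at least two genes")
    if (length(msg)) msg else TRUE
})

#' Thresholded gene functional-association network
#'
#' Undirected weighted graph in which nodes are genes and an edge joins two
#' genes whose similarity score is strictly greater than the edge similarity
#' threshold. Isolated genes are kept as nodes.
#'
#' @slot nodes gene ids.
#' @slot edges data.frame with columns gene1, gene2, score; one row per
#'   unordered pair, no self loops, every score > threshold.
#' @slot threshold the edge similarity threshold applied.
#' @slot measure name of the measure the scores came from.
#'
#' @seealso [buildNetwork()], [selectSubnetwork()], [exportNetwork()]
#' @export
setClass("AssociationNetwork",
    representation(
        nodes     = "character",
        edges     = "data.frame",
        threshold = "numeric",
        measure   = "character"
    )
)

setValidity("AssociationNetwork", function(object) {
    msg <- character()
    e <- object@edges
    need <- c("gene1", "gene2", "score")
    if (!all(need %in% names(e)))
        msg <- c(msg, "edges need columns gene1, gene2, score")
    else if (nrow(e)) {
        if (any(e$gene1 == e$gene2))
            msg <- c(msg, "self loops are not allowed")
        if (any(e$score <= object@threshold))
            msg <- c(msg, "every edge score must be strictly greater than the threshold")
        key <- paste(pmin(e$gene1, e$gene2), pmax(e$gene1, e$gene2))
        if (anyDuplicated(key))
            msg <- c(msg, "each unordered pair may appear at most once")
        if (!all(c(e$gene1, e$gene2) %in% object@nodes))
            msg <- c(msg, "edge endpoints must be nodes")
    }
    if (length(msg)) msg else TRUE
})

#' Synthetic fixture specification
#'
#' Parameters of the deterministic fixture generators: ontology size and
#' shape, corpus size, and the EC-group layout with a within-group coherence
#' knob (probability that a group member draws its annotations from the
#' group's own term pool rather than uniformly from all pools).
#'
#' @slot nTerms number of ontology terms (>= 1).
#' @slot maxParents maximum parents per non-root term (>= 1).
#' @slot nGenes total number of genes (>= 1).
#' @slot annotationsPerGene direct annotations drawn per gene (>= 1).
#' @slot nEcGroups number of EC groups (>= 1; >= 2 for EC corpora).
#' @slot coherence within-group annotation coherence in [0, 1].
#' @slot seed RNG seed; identical spec + seed give byte-identical fixtures.
#'
#' @seealso [fixtureSpec()], [randomOntology()], [ecGroupedCorpus()]
#' @export
setClass("FixtureSpec",
    representation(
        nTerms             = "integer",
        maxParents         = "integer",
        nGenes             = "integer",
        annotationsPerGene = "integer",
        nEcGroups          = "integer",
        coherence          = "numeric",
        seed               = "integer"
    )
)

setValidity("FixtureSpec", function(object) {
    msg <- character()
    counts <- c(object@nTerms, object@maxParents, object@nGenes,
                object@annotationsPerGene, object@nEcGroups)
    if (any(is.na(counts)) || any(counts < 1L))
        msg <- c(msg, "all counts must be >= 1")
    if (is.na(object@coherence) || object@coherence < 0 || object@coherence > 1)
        msg <- c(msg, "coherence must lie in [0, 1]")
    if (is.na(object@seed))
        msg <- c(msg, "seed is required")
    if (length(msg)) msg else TRUE
})
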