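#' @describeIn OntologyDAG-class number of terms
#' @param x an \code{OntologyDAG}
#' @export
setMethod("length", "OntologyDAG", function(x) length(x@termIds))

#' Term accessions of an ontology
#'
#' @param dag an [OntologyDAG-class]
#' @return character vector of term ids
#' @export
termIds <- function(dag) dag@termIds

#' Namespace root of an ontology
#'
#' @param dag an [OntologyDAG-class]
#' @return the root term id
#' @export
ontologyRoot <- function(dag) dag@root

#' Annotated genes of a corpus
#'
#' @param corpus an [AnnotationCorpus-class]
#' @return character vector of gene ids (the set G whose size normalizes IC)
#' @export
annotatedGenes <- function(corpus) corpus@genes

#' Score matrix of a similarity result
#'
#' @param x a [GeneSimilarityMatrix-class]
#' @return symmetric numeric matrix with gene ids as dimnames
#' @export
simScores <- function(x) x@scores

#' Measure name of a similarity result
#'
#' @param x a [GeneSimilarityMatrix-class]
#' @return the measure registry name
#' @export
simMeasure <- function(x) x@measure

#' Genes skipped for lack of annotation
#'
#' @param x a [GeneSimilarityMatrix-class]
#' @return character vector of input genes that could not be scored
#' @export
skippedGenes <- function(x) x@skipped

#' Trained measure weights
#'
#' @param model an [IntegrationModel-class]
#' @return named numeric vector of per-measure weights (sum 1)
#' @export
modelWeights <- function(model) model@weights

#' Edge table of an association network
#'
#' @param network an [AssociationNetwork-class]
#' @return data.frame with columns gene1, gene2, score
#' @export
networkEdges <- function(network) network@edges

#' Node set of an association network
#'
#' @param network an [AssociationNetwork-class]
#' @return character vector of gene ids (isolated genes included)
#' @export
networkNodes <- function(network) network@nodes

#' @exportMethod show
setMethod("show", "OntologyDAG", function(object) {
    cat("OntologyDAG with", length(object@termIds), "terms\n")
    cat("  namespace:", object@namespace, "\n")
    cat("  root:", object@root, "\n")
    nrel <- table(factor(unlist(object@parentRels, use.names = FALSE),
                         levels = c("is_a", "part_of")))
    cat("  edges:", sum(nrel), sprintf("(is_a %d, part_of %d)\n",
        nrel[["is_a"]], nrel[["part_of"]]))
})

setMethod("show", "AnnotationCorpus", function(object) {
    cat("AnnotationCorpus:", length(object@genes), "genes,",
        length(object@termGenes), "annotated terms\n")
    cat("  namespace:", object@namespace, "\n")
    cat("  direct annotations:", sum(lengths(object@direct)),
        " propagated:", sum(lengths(object@propagated)), "\n")
})

setMethod("show", "GeneSimilarityMatrix", function(object) {
    cat("GeneSimilarityMatrix (", object@measure, "): ",
        length(object@genes), " genes, ",
        choose(length(object@genes), 2), " pairs\n", sep = "")
    if (length(object@skipped))
        cat("  skipped (no annotation):", length(object@skipped), "\n")
    if (!object@normalized)
        cat("  scores are unnormalized (raw counts)\n")
})

setMethod("show", "RankMatrix", function(object) {
    cat("RankMatrix:", nrow(object@pairs), "gene pairs x",
        length(object@measures), "measures\n")
    cat("  measures:", paste(object@measures, collapse = ", "), "\n")
})

setMethod("show", "SeedSelection", function(object) {
    cat("SeedSelection (delta =", object@delta, "):",
        nrow(object@selected), "pairs\n")
    cat("  mean measures selected per pair:",
        round(mean(rowSums(object@selected)), 2), "\n")
})

setMethod("show", "IntegrationModel", function(object) {
    cat("IntegrationModel over", length(object@weights), "measures\n")
    w <- round(object@weights, 4)
    cat(" ", paste(names(w), w, sep = "=", collapse = "  "), "\n")
    cat("  delta:", object@delta, " seed:", object@seed,
        " iterations:", object@iterations, "\n")
    cat("  objective (within - between):", round(object@objective, 4), "\n")
})

setMethod("show", "ECGroupedGenes", function(object) {
    tab <- table(object@groups)
    cat("ECGroupedGenes:", length(object@groups), "genes in",
        length(tab), "groups\n")
    cat(" ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
})

setMethod("show", "AssociationNetwork", function(object) {
    cat("AssociationNetwork:", length(object@nodes), "nodes,",
        nrow(object@edges), "edges\n")
    cat("  measure:", object@measure, " threshold >", object@threshold, "\n")
})

setMethod("show", "FixtureSpec", function(object) {
    cat("FixtureSpec: ", object@nTerms, " terms (<=", object@maxParents,
        " parents), ", object@nGenes, " genes x ",
        object@annotationsPerGene, " annotations, ",
        object@nEcGroups, " EC groups (coherence ",
        object@coherence, "), seed ", object@seed, "\n", sep = "")
})
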