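#' Gene measure registry
#'
#' Names of all gene-level similarity measures the package computes. The
#' first four aggregate a term-level measure over the genes' direct
#' annotation sets; simui/simgic/to compare propagated annotation sets
#' directly; intego2 is the integrative measure (see [intego2Matrix()]).
#'
#' @return character vector of measure names
#' @export
geneMeasures <- function() {
    c("resnik", "schlicker", "wang", "hrss", "simui", "simgic", "to",
      "intego2")
}

propagatedTerms <- function(corpus, g) {
    ts <- corpus@propagated[[g]]
    if (is.null(ts))
        stop("gene has no GO annotation: ", g, call. = FALSE)
    ts
}

directTerms <- function(corpus, g) {
    ts <- corpus@direct[[g]]
    if (is.null(ts) || !length(ts))
        stop("gene has no GO annotation: ", g, call. = FALSE)
    ts
}

#' simUI gene similarity
#'
#' Jaccard index of the two genes' propagated GO term sets:
#' \eqn{|T_1 \cap T_2| / |T_1 \cup T_2|}.
#'
#' @param corpus an [AnnotationCorpus-class]
#' @param g1,g2 annotated gene ids
#' @return numeric in [0, 1]
#' @examples
#' fx <- toyFixture()
#' simUI(fx$corpus, "g1", "g3")   # 0.5
#' @export
simUI <- function(corpus, g1, g2) {
    t1 <- propagatedTerms(corpus, g1)
    t2 <- propagatedTerms(corpus, g2)
    length(intersect(t1, t2)) / length(union(t1, t2))
}

#' simGIC gene similarity
#'
#' IC-weighted Jaccard over propagated term sets:
#' \eqn{\sum_{t \in T_1 \cap T_2} IC(t) / \sum_{t \in T_1 \cup T_2} IC(t)}.
#' When both genes are annotated only to the root (zero total IC) the
#' similarity is defined as 0.
#'
#' @inheritParams simUI
#' @return numeric in [0, 1]
#' @export
simGIC <- function(corpus, g1, g2) {
    t1 <- propagatedTerms(corpus, g1)
    t2 <- propagatedTerms(corpus, g2)
    den <- sum(corpus@ic[union(t1, t2)])
    if (den == 0) return(0)
    sum(corpus@ic[intersect(t1, t2)]) / den
}

#' Term-overlap gene similarity
#'
#' Count of shared propagated GO terms, \eqn{|T_1 \cap T_2|}. Returned raw
#' (an integer, not normalized to [0, 1]); network thresholds on TO are
#' therefore in count units.
#'
#' @inheritParams simUI
#' @return non-negative integer
#' @export
simTO <- function(corpus, g1, g2) {
    length(intersect(propagatedTerms(corpus, g1),
                     propagatedTerms(corpus, g2)))
}

#' Aggregate a term-level measure to gene level
#'
#' Scores every pair of directly annotated terms with the chosen term
#' measure and aggregates with the best-match average (default): each
#' term's best match in the other gene's set, averaged over both
#' directions. Direct (not propagated) annotation sets are used so that
#' shared ancestors are not double-counted inside the average.
#'
#' @param corpus an [AnnotationCorpus-class]
#' @param dag the matching [OntologyDAG-class]
#' @param g1,g2 annotated gene ids
#' @param termMeasure one of \code{"resnik"}, \code{"schlicker"},
#'   \code{"wang"}, \code{"hrss"}
#' @param strategy \code{"bma"} (best-match average, default) or
#'   \code{"max"}
#' @param ... passed to the term measure (\code{weights}, \code{dist})
#' @return numeric score on the term measure's scale
#' @examples
#' fx <- toyFixture()
#' aggregateTermMeasure(fx$corpus, fx$dag, "g1", "g3", "wang")
#' @export
aggregateTermMeasure <- function(corpus, dag, g1, g2,
                                 termMeasure = c("resnik", "schlicker",
                                                 "wang", "hrss"),
                                 strategy = c("bma", "max"), ...) {
    termMeasure <- match.arg(termMeasure)
    strategy <- match.arg(strategy)
    fun <- termMeasureFun(termMeasure)
    t1 <- directTerms(corpus, g1)
    t2 <- directTerms(corpus, g2)
    s <- matrix(0, length(t1), length(t2))
    for (i in seq_along(t1))
        for (j in seq_along(t2))
            s[i, j] <- fun(corpus, dag, t1[[i]], t2[[j]], ...)
    if (strategy == "max") return(max(s))
    (sum(apply(s, 1L, max)) + sum(apply(s, 2L, max))) /
        (length(t1) + length(t2))
}

# Single-pair dispatcher over the seed-measure registry (intego2 excluded:
# it is defined over a whole pair set, not a single pair).
geneSimFun <- function(measure) {
    switch(measure,
        simui  = function(corpus, dag, g1, g2, ...) simUI(corpus, g1, g2),
        simgic = function(corpus, dag, g1, g2, ...) simGIC(corpus, g1, g2),
        to     = function(corpus, dag, g1, g2, ...) simTO(corpus, g1, g2),
        resnik = , schlicker = , wang = , hrss = {
            m <- measure
            function(corpus, dag, g1, g2, ...)
                aggregateTermMeasure(corpus, dag, g1, g2, m, ...)
        },
        stop("unknown gene measure: ", measure, call. = FALSE))
}

measureIsNormalized <- function(measure) {
    !(measure %in% c("resnik", "to"))
}

#' Pairwise gene similarity matrix for one measure
#'
#' Scores all unordered pairs of the input genes with one seed measure.
#' Input genes without GO annotation are dropped and reported in the
#' result's skipped-gene list; at least two annotated genes are required.
#' Diagonal entries hold self-similarities.
#'
#' @param corpus an [AnnotationCorpus-class]
#' @param genes character vector of gene ids (>= 2)
#' @param measure a seed measure name from [geneMeasures()]
#'   (\code{"intego2"} has its own entry point, [intego2Matrix()])
#' @param dag the [OntologyDAG-class]; required for the term-aggregated
#'   measures (resnik/schlicker/wang/hrss)
#' @param ... passed through to the measure (\code{strategy},
#'   \code{weights}, \code{dist})
#' @return a [GeneSimilarityMatrix-class]
#' @examples
#' fx <- toyFixture()
#' m <- geneSimMatrix(fx$corpus, c("g1", "g3", "g4"), "simui")
#' simScores(m)
#' @export
geneSimMatrix <- function(corpus, genes, measure, dag = NULL, ...) {
    measure <- match.arg(measure, setdiff(geneMeasures(), "intego2"))
    if (measure %in% c("resnik", "schlicker", "wang", "hrss") && is.null(dag))
        stop("dag is required for term-aggregated measures", call. = FALSE)
    genes <- unique(genes)
    annotated <- genes %in% names(corpus@direct)
    skipped <- genes[!annotated]
    genes <- genes[annotated]
    if (length(genes) < 2L)
        stop("fewer than two annotated genes (",
             length(skipped), " skipped for lack of annotation)",
             call. = FALSE)
    fun <- geneSimFun(measure)
    n <- length(genes)
    s <- matrix(0, n, n, dimnames = list(genes, genes))
    for (i in seq_len(n)) {
        for (j in i:n)
            s[i, j] <- s[j, i] <- fun(corpus, dag, genes[[i]], genes[[j]], ...)
    }
    new("GeneSimilarityMatrix", measure = measure, genes = genes,
        scores = s, normalized = measureIsNormalized(measure),
        skipped = skipped)
}

#' Score an explicit list of gene pairs
#'
#' Pair-list mode: only the listed pairs are computed, not the full matrix.
#' Pairs with an unannotated member are skipped and reported.
#'
#' @inheritParams geneSimMatrix
#' @param pairs data.frame (or two-column matrix) of gene1, gene2
#' @return list with \code{scores} (data.frame gene1, gene2, score,
#'   measure) and \code{skipped} (genes lacking annotation)
#' @export
geneSimPairs <- function(corpus, pairs, measure, dag = NULL, ...) {
    measure <- match.arg(measure, setdiff(geneMeasures(), "intego2"))
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    names(pairs)[1:2] <- c("gene1", "gene2")
    fun <- geneSimFun(measure)
    annotated <- function(g) g %in% names(corpus@direct)
    skipped <- unique(c(pairs$gene1, pairs$gene2))
    skipped <- skipped[!annotated(skipped)]
    ok <- annotated(pairs$gene1) & annotated(pairs$gene2)
    kept <- pairs[ok, , drop = FALSE]
    if (!nrow(kept))
        stop("no scorable pairs: all genes lack annotation", call. = FALSE)
    score <- mapply(function(a, b) fun(corpus, dag, a, b, ...),
                    kept$gene1, kept$gene2)
    list(scores = data.frame(gene1 = kept$gene1, gene2 = kept$gene2,
                             score = unname(score), measure = measure,
                             stringsAsFactors = FALSE),
         skipped = skipped)
}

#' Write pair scores as TSV
#'
#' Tab-separated with header \code{gene1 gene2 score measure}; rows sorted
#' by gene pair for byte-stable output.
#'
#' @param x a [GeneSimilarityMatrix-class] or the \code{scores} data.frame
#'   of [geneSimPairs()]
#' @param path output path
#' @return invisibly, the path
#' @export
writeSimTSV <- function(x, path) {
    if (is(x, "GeneSimilarityMatrix")) {
        df <- unorderedPairs(x@genes)
        df$score <- pairScoresVector(x@scores)
        df$measure <- x@measure
    } else df <- x
    df <- df[order(df$gene1, df$gene2), , drop = FALSE]
    df$score <- sprintf("%.10g", df$score)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read pair scores written by [writeSimTSV()]
#'
#' @param path a TSV with header \code{gene1 gene2 score measure}
#' @return data.frame with those columns
#' @export
readSimTSV <- function(path) {
    df <- tryCatch(
        utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "numeric", "character")),
        error = function(e) stop("malformed similarity TSV ", path, ": ",
                                 conditionMessage(e), call. = FALSE))
    need <- c("gene1", "gene2", "score", "measure")
    if (!all(need %in% names(df)))
        stop("similarity TSV must have columns gene1, gene2, score, measure",
             call. = FALSE)
    df
}

#' Rebuild a similarity matrix from long-format pair scores
#'
#' Inverse of [writeSimTSV()] for a complete pair set: the unordered pairs
#' must cover all gene combinations of one measure. Diagonal entries are
#' set to 1 for normalized measures and NA otherwise (raw-count scales
#' have no canonical self score).
#'
#' @param df data.frame with columns gene1, gene2, score, measure
#' @return a [GeneSimilarityMatrix-class]
#' @export
simMatrixFromPairs <- function(df) {
    genes <- sort(unique(c(df$gene1, df$gene2)))
    n <- length(genes)
    measure <- unique(df$measure)
    if (length(measure) != 1L)
        stop("pair table mixes measures: ",
             paste(measure, collapse = ", "), call. = FALSE)
    if (nrow(df) != choose(n, 2L))
        stop("pair table does not cover all unordered pairs of its genes",
             call. = FALSE)
    s <- matrix(0, n, n, dimnames = list(genes, genes))
    diag(s) <- if (measureIsNormalized(measure)) 1 else NA_real_
    for (k in seq_len(nrow(df))) {
        s[df$gene1[[k]], df$gene2[[k]]] <- df$score[[k]]
        s[df$gene2[[k]], df$gene1[[k]]] <- df$score[[k]]
    }
    new("GeneSimilarityMatrix", measure = measure, genes = genes,
        scores = s, normalized = measureIsNormalized(measure),
        skipped = character())
}
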