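#' Build the per-measure rank matrix over gene pairs
#'
#' First step of the integrative measure: every candidate measure's raw
#' scores over the same unordered gene pairs are converted to descending
#' ranks (rank 1 = most similar; ties get the mean of the tied positions)
#' and to normalized rank scores r' = 1 - (rank - 1)/(N - 1). Ranking makes
#' measures with incomparable raw scales (IC units, counts, [0,1] scores)
#' directly comparable, and is invariant to any strictly monotone transform
#' of a measure's raw scores.
#'
#' @param matrices list of [GeneSimilarityMatrix-class] objects over the
#'   same genes (names default to each matrix's measure).
#' @return a [RankMatrix-class]
#' @examples
#' fx <- toyFixture()
#' g <- paste0("g", 1:4)
#' rm <- buildRankMatrix(list(
#'     geneSimMatrix(fx$corpus, g, "simui"),
#'     geneSimMatrix(fx$corpus, g, "simgic")))
#' rm
#' @export
buildRankMatrix <- function(matrices) {
    if (!length(matrices))
        stop("at least one similarity matrix is required", call. = FALSE)
    nm <- names(matrices)
    if (is.null(nm))
        nm <- vapply(matrices, simMeasure, character(1))
    genes <- matrices[[1L]]@genes
    for (m in matrices)
        if (!setequal(m@genes, genes))
            stop("matrices cover different gene sets; cannot align pairs",
                 call. = FALSE)
    pairs <- unorderedPairs(sort(genes))
    np <- nrow(pairs)
    ranks <- vapply(matrices, function(m) {
        s <- m@scores[sort(genes), sort(genes)]
        rank(-pairScoresVector(s), ties.method = "average")
    }, numeric(np))
    ranks <- matrix(ranks, nrow = np,
                    dimnames = list(NULL, nm))
    rprime <- if (np > 1L) 1 - (ranks - 1) / (np - 1) else
        matrix(1, np, length(nm), dimnames = list(NULL, nm))
    new("RankMatrix", pairs = pairs, measures = nm,
        ranks = ranks, rprime = rprime)
}

rankPairIndex <- function(rankMatrix, pair) {
    if (is.numeric(pair)) return(as.integer(pair))
    a <- min(pair[[1L]], pair[[2L]]); b <- max(pair[[1L]], pair[[2L]])
    i <- which(rankMatrix@pairs$gene1 == a & rankMatrix@pairs$gene2 == b)
    if (!length(i))
        stop("pair not present in rank matrix: ", a, " / ", b, call. = FALSE)
    i
}

#' Select seed measures per gene pair
#'
#' The grouping step of the integrative measure: for each gene pair the
#' median rank across all candidate measures summarizes their consensus,
#' and a measure is selected as a seed for that pair when its rank falls
#' within delta * N of the median (N = number of pairs). Measures that
#' disagree strongly with the consensus on a pair are thereby excluded for
#' that pair only. If the window selects nothing, the single measure
#' nearest the median is used, so the selection is never empty.
#'
#' @param rankMatrix a [RankMatrix-class]
#' @param delta window half-width as a fraction of N, in (0, 1]
#' @return a [SeedSelection-class]
#' @export
selectSeedMeasures <- function(rankMatrix, delta = 0.2) {
    if (delta <= 0 || delta > 1)
        stop("delta must lie in (0, 1]", call. = FALSE)
    r <- rankMatrix@ranks
    np <- nrow(r)
    win <- delta * np
    med <- apply(r, 1L, stats::median)
    dev <- abs(r - med)
    sel <- dev <= win
    none <- which(rowSums(sel) == 0L)
    for (i in none) {
        k <- which.min(dev[i, ])  # deterministic: first of tied minima
        sel[i, k] <- TRUE
    }
    new("SeedSelection", selected = sel, delta = delta)
}

#' Integrated similarity of one gene pair
#'
#' The addition model: the weighted mean of the selected seed measures'
#' normalized rank scores,
#' \eqn{\sum_{m \in S} w_m r'_m / \sum_{m \in S} w_m}, using the model's
#' trained weights restricted to the pair's selected measures.
#'
#' @param model an [IntegrationModel-class]
#' @param rankMatrix a [RankMatrix-class]
#' @param selection a [SeedSelection-class] aligned with \code{rankMatrix}
#' @param pair a row index or a length-2 character vector of gene ids
#' @return numeric in [0, 1]
#' @export
integratePair <- function(model, rankMatrix, selection, pair) {
    i <- rankPairIndex(rankMatrix, pair)
    sel <- selection@selected[i, ]
    w <- model@weights[rankMatrix@measures]
    w[is.na(w)] <- 0
    w <- w * sel
    if (sum(w) == 0)
        stop("degenerate model: all selected measures have zero weight",
             call. = FALSE)
    sum(w * rankMatrix@rprime[i, ]) / sum(w)
}

# Vectorized integration of every pair; returns the integrated score
# vector in the rank matrix's pair order.
integrateAll <- function(weights, rankMatrix, selection) {
    w <- weights[rankMatrix@measures]
    w[is.na(w)] <- 0
    wsel <- sweep(selection@selected, 2L, w, `*`)
    den <- rowSums(wsel)
    if (any(den == 0))
        stop("degenerate model: all selected measures have zero weight ",
             "for some pair", call. = FALSE)
    rowSums(wsel * rankMatrix@rprime) / den
}

# Assemble integrated pair scores into a GeneSimilarityMatrix
# (diagonal = 1: a gene is maximally similar to itself).
integrateMatrix <- function(weights, rankMatrix, selection) {
    scores <- integrateAll(weights, rankMatrix, selection)
    genes <- sort(unique(c(rankMatrix@pairs$gene1, rankMatrix@pairs$gene2)))
    n <- length(genes)
    s <- matrix(0, n, n, dimnames = list(genes, genes))
    diag(s) <- 1
    for (k in seq_len(nrow(rankMatrix@pairs))) {
        s[rankMatrix@pairs$gene1[[k]], rankMatrix@pairs$gene2[[k]]] <-
            s[rankMatrix@pairs$gene2[[k]], rankMatrix@pairs$gene1[[k]]] <-
            scores[[k]]
    }
    new("GeneSimilarityMatrix", measure = "intego2", genes = genes,
        scores = s, normalized = TRUE, skipped = character())
}

#' EC-grouped training genes
#'
#' @param groups named character vector (gene id -> EC group label) or a
#'   two-column data.frame (gene, group)
#' @return an [ECGroupedGenes-class]
#' @export
ecGroups <- function(groups) {
    if (is.data.frame(groups)) {
        g <- as.character(groups[[2L]])
        names(g) <- as.character(groups[[1L]])
        groups <- g
    }
    new("ECGroupedGenes", groups = groups)
}

#' Read EC groups from a two-column TSV (gene<TAB>group)
#'
#' @param path input path; \code{#} comments allowed, no header
#' @return an [ECGroupedGenes-class]
#' @export
readECGroups <- function(path) {
    df <- utils::read.table(path, sep = "\t", comment.char = "#",
                            col.names = c("gene", "group"),
                            colClasses = "character")
    ecGroups(df)
}

#' Within- minus between-group mean similarity
#'
#' Separation statistic on an already-computed score matrix: the mean score
#' over gene pairs sharing an EC group minus the mean score over pairs from
#' distinct groups. Positive values mean the scores recover the functional
#' grouping.
#'
#' @param mat a [GeneSimilarityMatrix-class] covering all labelled genes
#' @param groups an [ECGroupedGenes-class]
#' @return numeric (difference of means)
#' @export
groupSeparation <- function(mat, groups) {
    g <- groups@groups
    stopIfAbsent(names(g), mat@genes, "labelled gene(s) in matrix")
    genes <- names(g)
    pairs <- unorderedPairs(genes)
    s <- mat@scores[cbind(pairs$gene1, pairs$gene2)]
    within <- g[pairs$gene1] == g[pairs$gene2]
    mean(s[within]) - mean(s[!within])
}

#' EC-group separation objective of a weight vector
#'
#' The training objective: integrate the candidate matrices with the given
#' weights (rank matrix, delta-window seed selection, weighted addition
#' model) and score the result with [groupSeparation()] on the EC-labelled
#' genes. Weight training maximizes this.
#'
#' @param weights named numeric vector, measure -> weight >= 0
#' @param delta grouping window in (0, 1]
#' @param matrices list of [GeneSimilarityMatrix-class] over the labelled
#'   genes
#' @param groups an [ECGroupedGenes-class]
#' @return numeric objective (mean within - mean between)
#' @export
separationObjective <- function(weights, delta, matrices, groups) {
    rm <- buildRankMatrix(matrices)
    sel <- selectSeedMeasures(rm, delta)
    groupSeparation(integrateMatrix(weights, rm, sel), groups)
}

#' Train integration weights by simulated annealing
#'
#' Learns the per-measure weights of the addition model from EC-grouped
#' training genes by maximizing [separationObjective()]. The search is a
#' seeded simulated annealing over the weight simplex: starting from
#' uniform weights, each iteration rescales one measure's weight by a
#' log-normal factor, renormalizes, and accepts by the Metropolis rule
#' under a geometrically cooled temperature. The best-seen state is kept,
#' so the trained objective is never below the uniform-weight objective.
#' With a single candidate measure the simplex is a point and the weight is
#' 1 without search.
#'
#' @param matrices list of [GeneSimilarityMatrix-class] over the labelled
#'   genes (the candidate measures)
#' @param groups an [ECGroupedGenes-class]; >= 2 groups of >= 2 genes
#' @param delta grouping window, fixed into the model for reuse at scoring
#'   time
#' @param iterations annealing iteration budget (>= 1)
#' @param cooling geometric cooling factor in (0, 1)
#' @param temp0 initial temperature
#' @param stepSd log-scale standard deviation of the weight proposal
#' @param seed RNG seed (required; recorded in the model)
#' @return an [IntegrationModel-class] with weights normalized to sum 1
#' @examples
#' fx <- ecGroupedCorpus(fixtureSpec(nGenes = 8, nEcGroups = 2, seed = 7))
#' mats <- list(geneSimMatrix(fx$corpus, names(fx$groups@groups), "simui"),
#'              geneSimMatrix(fx$corpus, names(fx$groups@groups), "simgic"))
#' trainWeights(mats, fx$groups, iterations = 200, seed = 1)
#' @export
trainWeights <- function(matrices, groups, delta = 0.2, iterations = 2000L,
                         cooling = 0.995, temp0 = 0.1, stepSd = 0.3,
                         seed) {
    if (missing(seed))
        stop("seed is required for reproducible training", call. = FALSE)
    iterations <- as.integer(iterations)
    if (is.na(iterations) || iterations < 1L)
        stop("search budget must be at least 1 iteration", call. = FALSE)
    validObject(groups)
    rm <- buildRankMatrix(matrices)
    sel <- selectSeedMeasures(rm, delta)
    measures <- rm@measures
    nm <- length(measures)

    # objective over the labelled genes, reusing the fixed rank matrix and
    # selection; works on the pair-score vector directly
    g <- groups@groups
    stopIfAbsent(names(g),
                 unique(c(rm@pairs$gene1, rm@pairs$gene2)),
                 "EC-labelled gene(s) in matrices")
    labelled <- rm@pairs$gene1 %in% names(g) & rm@pairs$gene2 %in% names(g)
    within <- labelled & g[rm@pairs$gene1] == g[rm@pairs$gene2]
    between <- labelled & !within
    obj <- function(w) {
        s <- integrateAll(w, rm, sel)
        mean(s[within]) - mean(s[between])
    }

    uniform <- structure(rep(1 / nm, nm), names = measures)
    if (nm == 1L) {
        return(new("IntegrationModel",
                   weights = structure(1, names = measures),
                   delta = delta, seed = as.integer(seed),
                   iterations = 0L, objective = obj(uniform)))
    }

    withLocalSeed(seed, {
        cur <- uniform
        fcur <- obj(cur)
        best <- cur; fbest <- fcur
        temp <- temp0
        for (it in seq_len(iterations)) {
            prop <- cur
            k <- sample.int(nm, 1L)
            prop[[k]] <- prop[[k]] * exp(stats::rnorm(1L, 0, stepSd))
            prop <- prop / sum(prop)
            fprop <- obj(prop)
            if (fprop >= fcur ||
                stats::runif(1L) < exp((fprop - fcur) / temp)) {
                cur <- prop; fcur <- fprop
            }
            if (fcur > fbest) { best <- cur; fbest <- fcur }
            temp <- temp * cooling
        }
        new("IntegrationModel", weights = best / sum(best), delta = delta,
            seed = as.integer(seed), iterations = iterations,
            objective = fbest)
    })
}

#' Integrative gene similarity matrix
#'
#' End-to-end integrative scoring of a gene set: compute every available
#' seed measure, rank them, select seeds per pair, and combine with the
#' addition model. Seed measures that fail on the corpus (for example a
#' term measure on genes with undefined IC) are dropped with a warning —
#' the integration is robust to unavailable candidates, and with a single
#' surviving measure it degenerates exactly to that measure's normalized
#' rank matrix.
#'
#' Weights come from \code{model} when given; otherwise they are trained
#' on \code{groups} when given, else uniform.
#'
#' @param corpus an [AnnotationCorpus-class]
#' @param genes gene ids to score (>= 2 annotated)
#' @param dag the matching [OntologyDAG-class]
#' @param model an [IntegrationModel-class], or NULL
#' @param groups optional [ECGroupedGenes-class] to train on (labelled
#'   genes must be among \code{genes})
#' @param measures candidate seed measures (default: all seven)
#' @param delta grouping window used when no model is supplied
#' @param seed training seed when no model is supplied
#' @param ... passed to [geneSimMatrix()] for the seed measures
#' @return a [GeneSimilarityMatrix-class] with measure \code{"intego2"}
#' @export
intego2Matrix <- function(corpus, genes, dag, model = NULL, groups = NULL,
                          measures = setdiff(geneMeasures(), "intego2"),
                          delta = 0.2, seed = 1L, ...) {
    mats <- list()
    for (m in measures) {
        mi <- tryCatch(geneSimMatrix(corpus, genes, m, dag = dag, ...),
                       error = function(e) e)
        if (inherits(mi, "error"))
            warning("seed measure ", m, " unavailable, dropped: ",
                    conditionMessage(mi), call. = FALSE)
        else mats[[m]] <- mi
    }
    if (!length(mats))
        stop("no seed measure could be computed for these genes",
             call. = FALSE)
    if (is.null(model)) {
        model <- if (!is.null(groups))
            trainWeights(mats, groups, delta = delta, seed = seed)
        else new("IntegrationModel",
                 weights = structure(rep(1 / length(mats), length(mats)),
                                     names = names(mats)),
                 delta = delta, seed = as.integer(seed), iterations = 0L,
                 objective = NA_real_)
    }
    rm <- buildRankMatrix(mats)
    sel <- selectSeedMeasures(rm, model@delta)
    out <- integrateMatrix(model@weights, rm, sel)
    out@skipped <- mats[[1L]]@skipped
    out
}

#' Write an integration model as flat JSON
#'
#' @param model an [IntegrationModel-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeIntegrationModel <- function(model, path) {
    jsonlite::write_json(
        list(weights = as.list(model@weights), delta = model@delta,
             seed = model@seed, iterations = model@iterations,
             objective = model@objective),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' Read an integration model written by [writeIntegrationModel()]
#'
#' @param path JSON model path
#' @return an [IntegrationModel-class]
#' @export
readIntegrationModel <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("IntegrationModel",
        weights = unlist(x$weights), delta = as.numeric(x$delta),
        seed = as.integer(x$seed), iterations = as.integer(x$iterations),
        objective = as.numeric(x$objective))
}
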