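#' Semantic-contribution edge weights for the Wang measure
#'
#' Per-relation contribution factors applied along each edge when
#' propagating a term's semantic contribution toward the root. The
#' conventional values of the Wang method are 0.8 for \code{is_a} and 0.6
#' for \code{part_of}; both must lie strictly between 0 and 1 so that
#' contributions decay along paths.
#'
#' @param isA contribution factor of \code{is_a} edges.
#' @param partOf contribution factor of \code{part_of} edges.
#' @return named numeric vector used by [wangSValues()] and [simWang()]
#' @export
edgeWeights <- function(isA = 0.8, partOf = 0.6) {
    if (isA <= 0 || isA >= 1 || partOf <= 0 || partOf >= 1)
        stop("edge weights must lie strictly between 0 and 1", call. = FALSE)
    c(is_a = isA, part_of = partOf)
}

#' Resnik term similarity
#'
#' Information content of the most informative common ancestor:
#' \eqn{-\ln(|G_{LCA}| / |G|)}. Zero when the only shared ancestor is the
#' root; unbounded above by \eqn{\ln |G|}.
#'
#' @param corpus an [AnnotationCorpus-class]
#' @param dag the matching [OntologyDAG-class]
#' @param ta,tb term ids with defined IC
#' @return non-negative numeric
#' @examples
#' fx <- toyFixture()
#' simResnik(fx$corpus, fx$dag, "A1", "A2")   # IC(A) = -ln(5/8)
#' @export
simResnik <- function(corpus, dag, ta, tb) {
    informationContent(corpus, mica(corpus, dag, ta, tb))
}

#' Schlicker term similarity
#'
#' The MICA's information content normalized by the terms' own IC and
#' damped by the MICA's annotation frequency:
#' \deqn{\frac{2\,IC(LCA)}{IC(t_a) + IC(t_b)}
#'       \times \left(1 - \frac{|G_{LCA}|}{|G|}\right)}
#' Root-against-root comparisons carry zero information and return 0.
#'
#' @inheritParams simResnik
#' @return numeric in [0, 1]
#' @export
simSchlicker <- function(corpus, dag, ta, tb) {
    icab <- informationContent(corpus, c(ta, tb))
    if (sum(icab) == 0) return(0)  # both root: zero information
    lca <- mica(corpus, dag, ta, tb)
    nLCA <- length(corpus@termGenes[[lca]])
    (2 * informationContent(corpus, lca) / sum(icab)) *
        (1 - nLCA / length(corpus@genes))
}

#' Wang semantic-contribution values of a term
#'
#' For each self-inclusive ancestor p of a term t, the S-value is the
#' maximal product of edge contribution factors over all paths from t up to
#' p (S-value of t itself is 1, the empty product). Computed by dynamic
#' programming on the DAG.
#'
#' @param dag an [OntologyDAG-class]
#' @param term a term id
#' @param weights per-relation contribution factors from [edgeWeights()]
#' @return named numeric vector over \code{ancestors(dag, term, TRUE)},
#'   values in (0, 1]
#' @examples
#' fx <- toyFixture()
#' wangSValues(fx$dag, "A1")   # A1 = 1, A = 0.8, R = 0.64
#' @export
wangSValues <- function(dag, term, weights = edgeWeights()) {
    term <- resolveTermId(dag, term)
    scope <- ancestors(dag, term, includeSelf = TRUE)
    s <- structure(rep(-Inf, length(scope)), names = scope)
    s[[term]] <- 1
    # topoOrder lists parents before children; walking it in reverse visits
    # every child before its parents, so each max is final when taken.
    for (t in rev(dag@topoOrder)) {
        if (!(t %in% scope) || t == term) next
        for (ch in dag@children[[t]]) {
            if (!(ch %in% scope)) next
            k <- match(t, dag@parents[[ch]])
            w <- weights[[dag@parentRels[[ch]][[k]]]]
            s[[t]] <- max(s[[t]], s[[ch]] * w)
        }
    }
    s
}

#' Wang term similarity
#'
#' Topology-based similarity: the semantic contributions that the two
#' terms' self-inclusive ancestor sets \eqn{P_a, P_b} share, over the total
#' contribution of both terms:
#' \deqn{\frac{\sum_{p \in P_a \cap P_b} (S_{t_a,p} + S_{t_b,p})}
#'            {\sum_{p \in P_a} S_{t_a,p} + \sum_{p \in P_b} S_{t_b,p}}}
#' Including each term in its own ancestor set makes self-similarity
#' exactly 1.
#'
#' @inheritParams wangSValues
#' @param ta,tb term ids
#' @return numeric in (0, 1] (the root is always shared)
#' @export
simWang <- function(dag, ta, tb, weights = edgeWeights()) {
    sa <- wangSValues(dag, ta, weights)
    sb <- wangSValues(dag, tb, weights)
    shared <- intersect(names(sa), names(sb))
    (sum(sa[shared]) + sum(sb[shared])) / (sum(sa) + sum(sb))
}

#' Hybrid relative specificity similarity (HRSS)
#'
#' Combines the depth of the most informative common ancestor (MICA) with
#' how far each term sits from its most informative leaf (MIL, the max-IC
#' childless descendant; ties broken by smallest id). With
#' \eqn{\alpha = IC(MICA)},
#' \eqn{\beta = \frac{(IC(MIL_a) - IC(t_a)) + (IC(MIL_b) - IC(t_b))}{2}} and
#' \eqn{\gamma = dist(MICA, t_a) + dist(MICA, t_b)}:
#' \deqn{Sim_{HRSS} = \frac{1}{1 + \gamma} \cdot \frac{\alpha}{\alpha + \beta}}
#' Distances default to the IC scale, \eqn{dist(x, y) = IC(y) - IC(x)} for
#' an ancestor x; \code{dist = "edges"} instead counts edges on the
#' shortest path. When \eqn{\alpha + \beta = 0} (root-only information) the
#' similarity is defined as 0.
#'
#' @inheritParams simResnik
#' @param dist distance scale for \eqn{\gamma}: \code{"ic"} (default) or
#'   \code{"edges"}.
#' @return numeric in [0, 1]
#' @export
simHRSS <- function(corpus, dag, ta, tb, dist = c("ic", "edges")) {
    dist <- match.arg(dist)
    m <- mica(corpus, dag, ta, tb)
    alpha <- informationContent(corpus, m)
    # Most informative leaf: max-IC annotated leaf below t (ties broken by
    # smallest id). Leaves without annotations have no IC and cannot be
    # "most informative"; when no annotated leaf exists the term itself is
    # its own most informative descendant (zero specificity gap).
    milIC <- function(t) {
        leaves <- leavesBelow(dag, t)
        ic <- corpus@ic[leaves]
        keep <- !is.na(ic)
        if (!any(keep)) return(informationContent(corpus, t))
        leaves <- leaves[keep]; ic <- ic[keep]
        best <- leaves[ic == max(ic)]
        unname(ic[[sort(best)[[1L]]]])
    }
    beta <- ((milIC(ta) - informationContent(corpus, ta)) +
             (milIC(tb) - informationContent(corpus, tb))) / 2
    gamma <- if (dist == "ic") {
        (informationContent(corpus, ta) - alpha) +
            (informationContent(corpus, tb) - alpha)
    } else {
        edgeDistance(dag, m, ta) + edgeDistance(dag, m, tb)
    }
    if (alpha + beta == 0) return(0)
    (1 / (1 + gamma)) * alpha / (alpha + beta)
}

# Minimum number of parent edges from `term` up to its ancestor `anc`.
edgeDistance <- function(dag, anc, term) {
    if (anc == term) return(0L)
    depth <- 0L
    frontier <- term
    repeat {
        frontier <- unique(unlist(dag@parents[frontier], use.names = FALSE))
        depth <- depth + 1L
        if (!length(frontier))
            stop(anc, " is not an ancestor of ", term, call. = FALSE)
        if (anc %in% frontier) return(depth)
    }
}

# Registry of term-level measures, used by the gene-level aggregator.
termMeasureFun <- function(measure) {
    switch(measure,
        resnik    = function(corpus, dag, ta, tb, ...)
            simResnik(corpus, dag, ta, tb),
        schlicker = function(corpus, dag, ta, tb, ...)
            simSchlicker(corpus, dag, ta, tb),
        wang      = function(corpus, dag, ta, tb, weights = edgeWeights(), ...)
            simWang(dag, ta, tb, weights),
        hrss      = function(corpus, dag, ta, tb, dist = "ic", ...)
            simHRSS(corpus, dag, ta, tb, dist),
        stop("unknown term measure: ", measure, call. = FALSE))
}
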