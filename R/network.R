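#' Build a thresholded gene functional-association network
#'
#' Nodes are the matrix's genes; an edge joins two genes whose similarity
#' is strictly greater than the edge similarity threshold ("greater than",
#' so ties at the threshold are excluded). Genes left without edges remain
#' as isolated nodes. A threshold above the maximum score yields a valid
#' empty-edge network with a warning.
#'
#' @param mat a [GeneSimilarityMatrix-class]
#' @param threshold edge similarity threshold, on the measure's own scale
#'   (count units for term overlap)
#' @return an [AssociationNetwork-class]
#' @examples
#' fx <- toyFixture()
#' m <- geneSimMatrix(fx$corpus, paste0("g", 1:5), "simui")
#' buildNetwork(m, 0.4)
#' @export
buildNetwork <- function(mat, threshold) {
    pairs <- unorderedPairs(mat@genes)
    pairs$score <- pairScoresVector(mat@scores)
    edges <- pairs[pairs$score > threshold, , drop = FALSE]
    rownames(edges) <- NULL
    if (!nrow(edges) && nrow(pairs) && threshold >= max(pairs$score))
        warning("threshold ", threshold,
                " is at or above the maximum pair score (",
                max(pairs$score), "); network has no edges", call. = FALSE)
    new("AssociationNetwork", nodes = mat@genes, edges = edges,
        threshold = threshold, measure = mat@measure)
}

#' Histogram of pair similarity scores
#'
#' Distribution of all unordered-pair scores of a similarity matrix, for
#' choosing an edge threshold. Counts always sum to the number of pairs,
#' C(n, 2).
#'
#' @param mat a [GeneSimilarityMatrix-class]
#' @param bins number of equal-width bins over the score range (>= 1), or
#'   an explicit vector of break points
#' @return data.frame with columns lower, upper, count
#' @export
scoreHistogram <- function(mat, bins = 10L) {
    s <- pairScoresVector(mat@scores)
    if (length(bins) == 1L) {
        if (bins < 1L) stop("bins must be >= 1", call. = FALSE)
        rng <- range(s)
        if (rng[[1L]] == rng[[2L]])
            rng <- rng + c(-0.5, 0.5)
        breaks <- seq(rng[[1L]], rng[[2L]], length.out = bins + 1L)
    } else breaks <- bins
    h <- graphics::hist(s, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = TRUE)
    data.frame(lower = h$breaks[-length(h$breaks)],
               upper = h$breaks[-1L], count = h$counts)
}

#' Select a subnetwork around genes of interest
#'
#' Induced subgraph on the requested genes, optionally extended first by
#' their direct neighbors (so selecting one gene with
#' \code{includeNeighbors = TRUE} pulls in that gene's partners and the
#' edges among the extended set). Requested genes absent from the network
#' are reported via [message()] and ignored.
#'
#' @param network an [AssociationNetwork-class]
#' @param genes genes of interest
#' @param includeNeighbors also include the direct neighbors of the
#'   selected genes?
#' @return an [AssociationNetwork-class]
#' @export
selectSubnetwork <- function(network, genes, includeNeighbors = FALSE) {
    unknown <- setdiff(genes, network@nodes)
    if (length(unknown))
        message("ignoring ", length(unknown),
                " gene(s) not in the network: ",
                paste(unknown, collapse = ", "))
    sel <- intersect(genes, network@nodes)
    e <- network@edges
    if (includeNeighbors && length(sel)) {
        nb <- c(e$gene2[e$gene1 %in% sel], e$gene1[e$gene2 %in% sel])
        sel <- union(sel, nb)
    }
    keep <- e$gene1 %in% sel & e$gene2 %in% sel
    edges <- e[keep, , drop = FALSE]
    rownames(edges) <- NULL
    new("AssociationNetwork", nodes = sel, edges = edges,
        threshold = network@threshold, measure = network@measure)
}

# igraph view of a network, used by the GraphML exporter. Node order and
# edge order are sorted so exports are byte-stable.
asIgraph <- function(network) {
    nodes <- sort(network@nodes)
    e <- network@edges
    if (nrow(e)) {
        g1 <- pmin(e$gene1, e$gene2); g2 <- pmax(e$gene1, e$gene2)
        o <- order(g1, g2)
        e <- data.frame(from = g1[o], to = g2[o], score = e$score[o],
                        stringsAsFactors = FALSE)
    } else e <- data.frame(from = character(), to = character(),
                           score = numeric())
    g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                       vertices = data.frame(name = nodes))
    g <- igraph::set_graph_attr(g, "threshold", network@threshold)
    igraph::set_graph_attr(g, "measure", network@measure)
}

networkFormats <- c("edge-tsv", "graphml", "cytoscape-json")

#' Export an association network
#'
#' Writes the network for downstream visualization. Output is
#' deterministic (nodes and edges sorted) and round-trips through
#' [importNetwork()]. Formats:
#' \describe{
#'   \item{edge-tsv}{tab-separated edge list with a commented header
#'     carrying nodes, threshold and measure, so isolated nodes survive
#'     the round trip.}
#'   \item{graphml}{GraphML via igraph, scores as an edge attribute.}
#'   \item{cytoscape-json}{the cytoscape.js \code{elements} dialect
#'     (\code{nodes}/\code{edges} with a \code{data} object; score as an
#'     edge data attribute), directly loadable by cytoscape.js fronts.}
#' }
#'
#' @param network an [AssociationNetwork-class]
#' @param format one of \code{"edge-tsv"}, \code{"graphml"},
#'   \code{"cytoscape-json"}
#' @param path output path
#' @return invisibly, the path
#' @export
exportNetwork <- function(network, format, path) {
    format <- match.arg(format, networkFormats)
    nodes <- sort(network@nodes)
    e <- network@edges
    if (nrow(e)) {
        g1 <- pmin(e$gene1, e$gene2); g2 <- pmax(e$gene1, e$gene2)
        o <- order(g1, g2)
        e <- data.frame(gene1 = g1[o], gene2 = g2[o], score = e$score[o],
                        stringsAsFactors = FALSE)
    }
    if (format == "edge-tsv") {
        hdr <- c(paste0("# measure: ", network@measure),
                 paste0("# threshold: ",
                        sprintf("%.10g", network@threshold)),
                 paste0("# nodes: ", paste(nodes, collapse = ",")),
                 "gene1\tgene2\tscore")
        rows <- if (nrow(e))
            sprintf("%s\t%s\t%.6f", e$gene1, e$gene2, e$score)
        else character()
        writeLines(c(hdr, rows), path)
    } else if (format == "graphml") {
        igraph::write_graph(asIgraph(network), path, format = "graphml")
    } else {
        el <- list(
            nodes = lapply(nodes, function(n) list(data = list(id = n))),
            edges = lapply(seq_len(nrow(e)), function(k)
                list(data = list(
                    id = paste0(e$gene1[[k]], "|", e$gene2[[k]]),
                    source = e$gene1[[k]], target = e$gene2[[k]],
                    score = e$score[[k]]))))
        jsonlite::write_json(
            list(measure = network@measure,
                 threshold = network@threshold,
                 elements = el),
            path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
    }
    invisible(path)
}

#' Import an association network written by [exportNetwork()]
#'
#' @param path input path
#' @param format the format it was written in
#' @return an [AssociationNetwork-class]
#' @export
importNetwork <- function(path, format) {
    format <- match.arg(format, networkFormats)
    if (format == "edge-tsv") {
        lines <- readLines(path, warn = FALSE)
        meta <- lines[startsWith(lines, "# ")]
        getMeta <- function(key) {
            m <- meta[startsWith(meta, paste0("# ", key, ": "))]
            if (!length(m)) return(NA_character_)
            sub(paste0("^# ", key, ": "), "", m[[1L]])
        }
        measure <- getMeta("measure")
        threshold <- as.numeric(getMeta("threshold"))
        nodes <- strsplit(getMeta("nodes"), ",", fixed = TRUE)[[1L]]
        body <- lines[!startsWith(lines, "#")]
        body <- body[nzchar(body)][-1L]  # drop column header
        if (length(body)) {
            parts <- strsplit(body, "\t", fixed = TRUE)
            edges <- data.frame(
                gene1 = vapply(parts, `[[`, character(1), 1L),
                gene2 = vapply(parts, `[[`, character(1), 2L),
                score = as.numeric(vapply(parts, `[[`, character(1), 3L)),
                stringsAsFactors = FALSE)
        } else edges <- data.frame(gene1 = character(), gene2 = character(),
                                   score = numeric())
        new("AssociationNetwork", nodes = nodes, edges = edges,
            threshold = threshold, measure = measure)
    } else if (format == "graphml") {
        g <- igraph::read_graph(path, format = "graphml")
        el <- igraph::as_data_frame(g, what = "edges")
        edges <- data.frame(gene1 = el$from, gene2 = el$to,
                            score = if (nrow(el)) el$score else numeric(),
                            stringsAsFactors = FALSE)
        new("AssociationNetwork",
            nodes = igraph::V(g)$name, edges = edges,
            threshold = igraph::graph_attr(g, "threshold"),
            measure = igraph::graph_attr(g, "measure"))
    } else {
        x <- jsonlite::read_json(path, simplifyVector = FALSE)
        nodes <- vapply(x$elements$nodes, function(n) n$data$id,
                        character(1))
        edges <- if (length(x$elements$edges)) data.frame(
            gene1 = vapply(x$elements$edges, function(e) e$data$source,
                           character(1)),
            gene2 = vapply(x$elements$edges, function(e) e$data$target,
                           character(1)),
            score = vapply(x$elements$edges, function(e)
                as.numeric(e$data$score), numeric(1)),
            stringsAsFactors = FALSE)
        else data.frame(gene1 = character(), gene2 = character(),
                        score = numeric())
        new("AssociationNetwork", nodes = nodes, edges = edges,
            threshold = as.numeric(x$threshold),
            measure = as.character(x$measure))
    }
}
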