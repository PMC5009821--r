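# Internal constructor: builds the derived structure (children map,
# topological order, ancestor closure) and validates acyclicity and
# single-rootedness.
newOntologyDAG <- function(ids, termNames, parents, parentRels,
                           namespace, altIds = character()) {
    names(termNames) <- ids
    parents    <- parents[ids]
    parentRels <- parentRels[ids]
    names(parents) <- names(parentRels) <- ids

    children <- lapply(ids, function(i) character())
    names(children) <- ids
    for (t in ids) {
        for (p in parents[[t]])
            children[[p]] <- c(children[[p]], t)
    }

    roots <- ids[lengths(parents) == 0L]
    if (length(roots) != 1L)
        stop("ontology must have exactly one root per namespace; found ",
             length(roots), if (length(roots)) paste0(
                 " (", paste(utils::head(roots, 5L), collapse = ", "), ")"),
             call. = FALSE)

    # Kahn's algorithm; failure to consume every term means a cycle.
    indeg <- lengths(parents)
    queue <- roots
    topo <- character(0)
    while (length(queue)) {
        t <- queue[[1L]]; queue <- queue[-1L]
        topo <- c(topo, t)
        for (ch in children[[t]]) {
            indeg[[ch]] <- indeg[[ch]] - 1L
            if (indeg[[ch]] == 0L) queue <- c(queue, ch)
        }
    }
    if (length(topo) != length(ids))
        stop("cycle detected in ontology graph involving: ",
             paste(utils::head(setdiff(ids, topo), 5L), collapse = ", "),
             call. = FALSE)

    anc <- lapply(ids, function(i) character())
    names(anc) <- ids
    for (t in topo) {
        ps <- parents[[t]]
        if (length(ps))
            anc[[t]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
    }

    new("OntologyDAG",
        namespace = namespace, termIds = ids, termNames = termNames,
        parents = parents, parentRels = parentRels, children = children,
        root = roots, ancestorSets = anc, topoOrder = topo,
        altIds = altIds)
}

resolveTermId <- function(dag, term) {
    if (term %in% dag@termIds) return(term)
    if (term %in% names(dag@altIds)) return(dag@altIds[[term]])
    stop("unknown term id: ", term, call. = FALSE)
}

#' Parse an OBO ontology file into a DAG
#'
#' Reads an OBO 1.2/1.4 flat file and returns the requested namespace as an
#' [OntologyDAG-class]. Obsolete terms are discarded (with their edges), as
#' are terms of other namespaces; \code{is_a} and \code{relationship:
#' part_of} edges are retained and every other relationship type
#' (\code{regulates}, \code{has_part}, ...) is dropped, matching mainstream
#' GO-similarity practice. Secondary accessions (\code{alt_id}) resolve to
#' their canonical id. Dropped obsolete terms and cross-namespace or
#' dangling parent links are reported via [message()].
#'
#' @param path path to an OBO file.
#' @param namespace namespace to load: \code{"MF"}, \code{"BP"},
#'   \code{"CC"} or a long form such as \code{"molecular_function"}.
#' @return an [OntologyDAG-class]
#' @examples
#' fx <- toyFixture()
#' obo <- tempfile(fileext = ".obo")
#' writeOBO(fx$dag, obo)
#' dag <- parseOBO(obo, "MF")
#' length(dag)
#' @export
parseOBO <- function(path, namespace = "MF") {
    if (!file.exists(path))
        stop("OBO file not found: ", path, call. = FALSE)
    namespace <- namespaceFromCode(namespace)
    lines <- readLines(path, warn = FALSE)

    defaultNs <- namespace
    stanzaStart <- 0L
    inTerm <- FALSE
    cur <- NULL
    terms <- list()

    flush <- function(cur, stanzaStart) {
        if (is.null(cur)) return(NULL)
        if (is.null(cur$id))
            stop("malformed [Term] stanza starting at line ", stanzaStart,
                 ": missing id", call. = FALSE)
        cur
    }

    for (i in seq_along(lines)) {
        line <- sub("\\s+$", "", lines[[i]])
        if (!nzchar(line)) next
        if (grepl("^\\[", line)) {
            t <- flush(cur, stanzaStart)
            if (!is.null(t)) terms[[t$id]] <- t
            cur <- NULL
            inTerm <- identical(line, "[Term]")
            if (inTerm) {
                cur <- list(parents = character(), rels = character(),
                            alt = character(), obsolete = FALSE,
                            namespace = NA_character_, name = "")
                stanzaStart <- i
            }
            next
        }
        m <- regmatches(line, regexec("^([A-Za-z_-]+):\\s*(.*)$", line))[[1L]]
        if (length(m) != 3L) {
            if (inTerm)
                stop("malformed stanza line ", i, ": ", line, call. = FALSE)
            next
        }
        key <- m[[2L]]; val <- m[[3L]]
        if (!inTerm) {
            if (key == "default-namespace") defaultNs <- val
            next
        }
        val <- sub("\\s*!.*$", "", val)  # strip trailing comments
        if (key == "id") cur$id <- val
        else if (key == "name") cur$name <- val
        else if (key == "namespace") cur$namespace <- val
        else if (key == "alt_id") cur$alt <- c(cur$alt, val)
        else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
        else if (key == "is_a") {
            if (!nzchar(val))
                stop("malformed stanza line ", i, ": empty is_a target",
                     call. = FALSE)
            cur$parents <- c(cur$parents, val)
            cur$rels <- c(cur$rels, "is_a")
        } else if (key == "relationship") {
            parts <- strsplit(trimws(val), "\\s+")[[1L]]
            if (length(parts) < 2L)
                stop("malformed stanza line ", i, ": ", line, call. = FALSE)
            if (parts[[1L]] == "part_of") {
                cur$parents <- c(cur$parents, parts[[2L]])
                cur$rels <- c(cur$rels, "part_of")
            }  # other relationship types dropped
        }
    }
    t <- flush(cur, stanzaStart)
    if (!is.null(t)) terms[[t$id]] <- t

    if (!length(terms))
        stop("no [Term] stanzas found in ", path, call. = FALSE)

    nObsolete <- sum(vapply(terms, `[[`, logical(1), "obsolete"))
    terms <- Filter(function(t) !t$obsolete, terms)
    ns <- vapply(terms, function(t)
        if (is.na(t$namespace)) defaultNs else t$namespace, character(1))
    terms <- terms[ns == namespace]
    if (!length(terms))
        stop("no non-obsolete terms in namespace ", namespace, call. = FALSE)
    if (nObsolete)
        message("dropped ", nObsolete, " obsolete term(s)")

    ids <- names(terms)
    altIds <- unlist(unname(lapply(terms, function(t) {
        structure(rep(t$id, length(t$alt)), names = t$alt)
    })))
    if (is.null(altIds)) altIds <- character()

    nDroppedEdges <- 0L
    parents <- list(); rels <- list()
    for (id in ids) {
        keep <- terms[[id]]$parents %in% ids
        nDroppedEdges <- nDroppedEdges + sum(!keep)
        parents[[id]] <- unname(terms[[id]]$parents[keep])
        rels[[id]] <- unname(terms[[id]]$rels[keep])
    }
    if (nDroppedEdges)
        message("dropped ", nDroppedEdges,
                " parent link(s) to obsolete or out-of-namespace terms")

    newOntologyDAG(ids,
                   vapply(terms, `[[`, character(1), "name"),
                   parents, rels, namespace, altIds)
}

#' Write an ontology DAG back to OBO format
#'
#' Deterministic output (terms sorted by id) so that fixtures are
#' reproducible byte-for-byte; parsing the file back recovers the DAG.
#'
#' @param dag an [OntologyDAG-class]
#' @param path output file path
#' @return invisibly, the path
#' @export
writeOBO <- function(dag, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("format-version: 1.2",
                 paste0("default-namespace: ", dag@namespace), ""), con)
    for (id in sort(dag@termIds)) {
        out <- c("[Term]",
                 paste0("id: ", id),
                 paste0("name: ", dag@termNames[[id]]),
                 paste0("namespace: ", dag@namespace))
        ps <- dag@parents[[id]]; rs <- dag@parentRels[[id]]
        if (length(ps)) {
            o <- order(ps)
            for (k in o) {
                out <- c(out, if (rs[[k]] == "is_a")
                    paste0("is_a: ", ps[[k]])
                else paste0("relationship: part_of ", ps[[k]]))
            }
        }
        writeLines(c(out, ""), con)
    }
    invisible(path)
}

#' Ancestors of a term
#'
#' Transitive closure of the parent relation (over \code{is_a} and
#' \code{part_of}) for one term.
#'
#' @param dag an [OntologyDAG-class]
#' @param term a term id (secondary accessions are resolved)
#' @param includeSelf include the term itself in the returned set?
#' @return character vector of term ids
#' @examples
#' fx <- toyFixture()
#' ancestors(fx$dag, "A1")            # A and the root
#' ancestors(fx$dag, "A1", TRUE)
#' @export
ancestors <- function(dag, term, includeSelf = FALSE) {
    term <- resolveTermId(dag, term)
    anc <- dag@ancestorSets[[term]]
    if (includeSelf) unique(c(term, anc)) else anc
}

# Descendants (children closure), optionally including the term itself.
descendants <- function(dag, term, includeSelf = FALSE) {
    term <- resolveTermId(dag, term)
    seen <- character()
    queue <- dag@children[[term]]
    while (length(queue)) {
        t <- queue[[1L]]; queue <- queue[-1L]
        if (t %in% seen) next
        seen <- c(seen, t)
        queue <- c(queue, dag@children[[t]])
    }
    if (includeSelf) unique(c(term, seen)) else seen
}

#' Common ancestors of two terms
#'
#' Intersection of the two self-inclusive ancestor sets; never empty, since
#' both terms share the namespace root.
#'
#' @param dag an [OntologyDAG-class]
#' @param ta,tb term ids in the same namespace
#' @return character vector of term ids
#' @export
commonAncestors <- function(dag, ta, tb) {
    intersect(ancestors(dag, ta, includeSelf = TRUE),
              ancestors(dag, tb, includeSelf = TRUE))
}

#' Leaf descendants of a term
#'
#' All childless descendants of a term; a childless term returns itself.
#' These are the candidate "most informative child leaf" terms of the
#' hybrid relative specificity similarity.
#'
#' @param dag an [OntologyDAG-class]
#' @param term a term id
#' @return character vector of leaf term ids
#' @export
leavesBelow <- function(dag, term) {
    below <- descendants(dag, term, includeSelf = TRUE)
    below[lengths(dag@children[below]) == 0L]
}
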