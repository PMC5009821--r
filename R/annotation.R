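#' Build an annotation corpus from direct gene-to-term annotations
#'
#' Applies the true path rule (a gene annotated to a term is implicitly
#' annotated to every ancestor of that term), inverts the propagated map,
#' and computes the information-content table
#' IC(t) = -ln(|G_t| / |G|) in natural-log units, where |G| is the number
#' of genes with at least one annotation in the loaded namespace. IC of the
#' root is exactly 0 and IC never decreases from parent to child.
#'
#' @param dag the [OntologyDAG-class] the term ids live in.
#' @param direct named list, gene id -> character vector of directly
#'   annotated term ids (secondary accessions are resolved).
#' @return an [AnnotationCorpus-class]
#' @examples
#' fx <- toyFixture()
#' corpus <- annotationCorpus(fx$dag, list(x = "A1", y = c("A2", "B1")))
#' informationContent(corpus, ontologyRoot(fx$dag))
#' @export
annotationCorpus <- function(dag, direct) {
    if (!length(direct) || is.null(names(direct)))
        stop("direct must be a non-empty named list (gene -> term ids)",
             call. = FALSE)
    direct <- lapply(direct, function(ts)
        unique(vapply(ts, function(t) resolveTermId(dag, t), character(1),
                      USE.NAMES = FALSE)))
    keep <- lengths(direct) > 0L
    if (!any(keep))
        stop("no annotated genes remain in the corpus", call. = FALSE)
    direct <- direct[keep]

    propagated <- lapply(direct, function(ts)
        unique(c(ts, unlist(dag@ancestorSets[ts], use.names = FALSE))))

    genes <- names(direct)
    termGenes <- list()
    for (g in genes)
        for (t in propagated[[g]])
            termGenes[[t]] <- c(termGenes[[t]], g)

    n <- length(genes)
    ic <- -log(lengths(termGenes) / n)
    ic[ic < 0] <- 0  # guard against -0 / rounding at the root

    new("AnnotationCorpus",
        direct = direct, propagated = propagated, termGenes = termGenes,
        genes = genes, ic = ic, namespace = dag@namespace, root = dag@root)
}

#' Parse a GAF 2.x annotation file
#'
#' Reads a GO Annotation File (tab-separated, 15--17 columns, \code{!}
#' comment lines), keyed by database object id (column 2). Rows with a NOT
#' qualifier are dropped, as are rows whose evidence code is excluded or
#' whose term is absent from the loaded DAG (reported via [message()]);
#' propagation and the IC table are then built with [annotationCorpus()].
#'
#' @param path path to a GAF file.
#' @param dag the [OntologyDAG-class] for the target namespace; rows from
#'   other namespaces are dropped as absent terms.
#' @param evidenceExclude character vector of evidence codes to drop
#'   (e.g. \code{"IEA"}); default keeps everything.
#' @return an [AnnotationCorpus-class]
#' @export
parseGAF <- function(path, dag, evidenceExclude = character()) {
    if (!file.exists(path))
        stop("GAF file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    if (!length(lines))
        stop("GAF file contains no annotation rows: ", path, call. = FALSE)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nc <- lengths(fields)
    bad <- which(nc < 15L | nc > 17L)
    if (length(bad))
        stop("GAF parse error: row ", bad[[1L]], " has ", nc[[bad[[1L]]]],
             " columns (expected 15-17)", call. = FALSE)

    gene     <- vapply(fields, `[[`, character(1), 2L)
    qualifier<- vapply(fields, `[[`, character(1), 4L)
    term     <- vapply(fields, `[[`, character(1), 5L)
    evidence <- vapply(fields, `[[`, character(1), 7L)

    keep <- !grepl("(^|\\|)NOT(\\||$)", qualifier)
    if (length(evidenceExclude))
        keep <- keep & !(evidence %in% evidenceExclude)
    gene <- gene[keep]; term <- term[keep]

    known <- term %in% dag@termIds | term %in% names(dag@altIds)
    if (any(!known))
        message("dropped ", sum(!known),
                " annotation row(s) with terms absent from the DAG")
    gene <- gene[known]; term <- term[known]
    if (!length(gene))
        stop("no usable annotation rows remain after filtering", call. = FALSE)

    annotationCorpus(dag, split(term, factor(gene, levels = unique(gene))))
}

#' Parse a plain two-column gene--term table
#'
#' Lightweight alternative to GAF: tab-separated \code{gene<TAB>term}, one
#' annotation per row, \code{#} comment lines allowed.
#'
#' @inheritParams parseGAF
#' @return an [AnnotationCorpus-class]
#' @export
parseAnnotationsTSV <- function(path, dag) {
    if (!file.exists(path))
        stop("annotation file not found: ", path, call. = FALSE)
    df <- utils::read.table(path, sep = "\t", comment.char = "#",
                            col.names = c("gene", "term"),
                            colClasses = "character", fill = FALSE)
    known <- df$term %in% dag@termIds | df$term %in% names(dag@altIds)
    if (any(!known))
        message("dropped ", sum(!known),
                " annotation row(s) with terms absent from the DAG")
    df <- df[known, , drop = FALSE]
    if (!nrow(df))
        stop("no usable annotation rows remain after filtering", call. = FALSE)
    annotationCorpus(dag,
                     split(df$term, factor(df$gene, levels = unique(df$gene))))
}

#' Write a corpus's direct annotations as GAF 2.2
#'
#' Deterministic (rows sorted by gene then term) so fixture files are
#' byte-stable; re-parsing reproduces identical propagated sets.
#'
#' @param corpus an [AnnotationCorpus-class]
#' @param path output file path
#' @param evidence evidence code written on every row
#' @return invisibly, the path
#' @export
writeGAF <- function(corpus, path, evidence = "EXP") {
    aspect <- aspectFromNamespace(corpus@namespace)
    rows <- character()
    for (g in sort(names(corpus@direct))) {
        for (t in sort(corpus@direct[[g]])) {
            rows <- c(rows, paste(
                "SYN", g, g, "enables", t, "SYN_REF:0000001", evidence, "",
                aspect, g, "", "protein", "taxon:32644", "20260101", "SYN",
                "", "",
                sep = "\t"))
        }
    }
    writeLines(c("!gaf-version: 2.2", rows), path)
    invisible(path)
}

#' Information content of a term
#'
#' IC(t) = -ln(|G_t| / |G|) over propagated annotations, in nats. Defined
#' only for terms carrying at least one propagated annotation; the caller
#' decides the fallback for unannotated terms.
#'
#' @param corpus an [AnnotationCorpus-class]
#' @param term a term id
#' @return non-negative numeric; exactly 0 for the root
#' @export
informationContent <- function(corpus, term) {
    ic <- corpus@ic[term]
    if (anyNA(ic))
        stop("IC undefined for term(s) without annotations: ",
             paste(term[is.na(ic)], collapse = ", "), call. = FALSE)
    unname(ic)
}

#' Most informative common ancestor
#'
#' The common ancestor of two terms with maximal information content; this
#' realizes the "lowest common ancestor" of IC-based measures in DAG form,
#' where "lowest" is ambiguous. Ties are broken by the lexicographically
#' smallest term id, making the choice deterministic.
#'
#' @param corpus an [AnnotationCorpus-class] supplying IC
#' @param dag the matching [OntologyDAG-class]
#' @param ta,tb term ids with defined IC
#' @return a single term id
#' @examples
#' fx <- toyFixture()
#' mica(fx$corpus, fx$dag, "A1", "A2")  # "A"
#' @export
mica <- function(corpus, dag, ta, tb) {
    ca <- commonAncestors(dag, ta, tb)
    ic <- corpus@ic[ca]
    if (anyNA(ic))
        stop("IC undefined for common ancestor(s): ",
             paste(ca[is.na(ic)], collapse = ", "), call. = FALSE)
    best <- ca[ic == max(ic)]
    sort(best)[[1L]]
}
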