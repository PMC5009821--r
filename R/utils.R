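# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so package randomness never leaks into the
# user's session.
withLocalSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("seed must be a single integer")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# All unordered pairs (i < j) of a character vector, as a data.frame.
unorderedPairs <- function(genes) {
    n <- length(genes)
    if (n < 2L)
        return(data.frame(gene1 = character(), gene2 = character(),
                          stringsAsFactors = FALSE))
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    data.frame(gene1 = genes[idx[, 1L]], gene2 = genes[idx[, 2L]],
               stringsAsFactors = FALSE)
}

# Vector of pair scores (i < j order matching unorderedPairs) from a
# symmetric score matrix.
pairScoresVector <- function(scores) {
    scores[upper.tri(scores)]
}

stopIfAbsent <- function(ids, universe, what) {
    missing <- setdiff(ids, universe)
    if (length(missing))
        stop("unknown ", what, ": ", paste(missing, collapse = ", "),
             call. = FALSE)
    invisible(TRUE)
}

namespaceFromCode <- function(code) {
    long <- c(MF = "molecular_function", BP = "biological_process",
              CC = "cellular_component")
    if (code %in% long) return(code)
    if (code %in% names(long)) return(long[[code]])
    stop("namespace must be one of MF, BP, CC (or their long forms)",
         call. = FALSE)
}

aspectFromNamespace <- function(ns) {
    switch(ns,
        molecular_function = "F",
        biological_process = "P",
        cellular_component = "C",
        "F")
}
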