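# Shared internal helpers: node/edge keys, seeded RNG streams, TSV reading.

nodeKey <- function(gene, type) paste(gene, type, sep = "@")

splitNodeKey <- function(key) {
    parts <- strsplit(key, "@", fixed = TRUE)
    data.frame(gene = vapply(parts, `[`, "", 1L),
               cell_type = vapply(parts, `[`, "", 2L),
               stringsAsFactors = FALSE)
}

# canonical undirected key; independent of endpoint order
edgeKey <- function(ed) {
    a <- nodeKey(ed$gene_a, ed$type_a)
    b <- nodeKey(ed$gene_b, ed$type_b)
    paste(pmin(a, b), pmax(a, b), sep = "--")
}

edgeKindFor <- function(type_a, type_b) {
    ifelse(type_a == type_b, "intracellular", "intercellular")
}

emptyEdges <- function() {
    data.frame(gene_a = character(), type_a = character(),
               gene_b = character(), type_b = character(),
               kind = character(), stringsAsFactors = FALSE)
}

emptyNodes <- function() {
    data.frame(gene = character(), cell_type = character(),
               stringsAsFactors = FALSE)
}

nodesFromEdges <- function(ed) {
    key <- unique(c(nodeKey(ed$gene_a, ed$type_a),
                    nodeKey(ed$gene_b, ed$type_b)))
    splitNodeKey(sort(key))
}

dedupEdges <- function(ed) {
    if (!nrow(ed)) return(ed)
    key <- edgeKey(ed)
    ed <- ed[!duplicated(key), , drop = FALSE]
    rownames(ed) <- NULL
    ed
}

# 31-bit polynomial string hash; keyed streams stay stable when unrelated
# patients are added to a cohort
stringHash31 <- function(s) {
    h <- 0
    for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
    as.integer(h)
}

streamSeed <- function(masterSeed, key, index = 0L) {
    as.integer((as.numeric(masterSeed) * 7919 + stringHash31(key) * 131 +
                as.numeric(index)) %% 2147483647)
}

# evaluate expr under a local RNG state so callers' streams are untouched
withSeed <- function(seed, expr) {
    hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hadSeed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (hadSeed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

readTsv <- function(path, header = TRUE, ...) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    utils::read.delim(path, header = header, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE, ...)
}

assertBinary <- function(x, what) {
    if (!all(x %in% c(0, 1)))
        stop(what, " must be a binary (0/1) vector", call. = FALSE)
    invisible(as.integer(x))
}
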