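# Independent oracles and fixture builders. Everything here is deliberately
# naive (exhaustive enumeration, plain BFS) and shares no code path with
# the implementations it checks.

nodeKeyT <- function(gene, type) paste(gene, type, sep = "@")

# canonical identity of an edge set: nodes in MCTC networks are identified
# by their (gene, cell type) label, so sorted undirected labeled edge
# strings are a complete isomorphism invariant -- independent of DFS codes
edgeSetKeyT <- function(ed) {
    a <- nodeKeyT(ed$gene_a, ed$type_a)
    b <- nodeKeyT(ed$gene_b, ed$type_b)
    paste(sort(paste(pmin(a, b), "~", pmax(a, b), "~", ed$kind)),
          collapse = " | ")
}

edgeSetConnected <- function(ed) {
    a <- nodeKeyT(ed$gene_a, ed$type_a)
    b <- nodeKeyT(ed$gene_b, ed$type_b)
    nodes <- unique(c(a, b))
    seen <- nodes[1]
    repeat {
        grow <- unique(c(b[a %in% seen], a[b %in% seen]))
        grow <- setdiff(grow, seen)
        if (!length(grow)) break
        seen <- c(seen, grow)
    }
    length(seen) == length(nodes)
}

# exhaustive frequent-subnetwork enumeration: every connected edge subset
# of every graph, tallied across graphs
bruteMine <- function(networks, minSupport, maxEdges) {
    perGraph <- lapply(networks, function(net) {
        ed <- netEdges(net)
        keys <- character()
        if (nrow(ed)) for (k in seq_len(min(maxEdges, nrow(ed)))) {
            for (idx in utils::combn(nrow(ed), k, simplify = FALSE)) {
                sub <- ed[idx, , drop = FALSE]
                if (edgeSetConnected(sub))
                    keys <- c(keys, edgeSetKeyT(sub))
            }
        }
        unique(keys)
    })
    ids <- vapply(networks, sampleId, "")
    tab <- table(unlist(perGraph))
    freq <- names(tab)[tab >= minSupport]
    support <- lapply(freq, function(k)
        sort(ids[vapply(perGraph, function(g) k %in% g, TRUE)]))
    names(support) <- freq
    support[order(freq)]
}

# mined pattern list -> the same representation as bruteMine
minedAsKeys <- function(patterns) {
    keys <- vapply(patterns, function(p) edgeSetKeyT(netEdges(p)), "")
    support <- lapply(patterns, function(p) sort(supportSet(p)))
    names(support) <- keys
    support[order(keys)]
}

randomNetwork <- function(id, nNodes = 6, nEdges = 6, genes = paste0("G", 1:5),
                          types = c("T1", "T2")) {
    grid <- expand.grid(gene = genes, cell_type = types,
                        stringsAsFactors = FALSE)
    pickN <- min(nNodes, nrow(grid))
    nd <- grid[sample.int(nrow(grid), pickN), , drop = FALSE]
    pairs <- utils::combn(pickN, 2, simplify = FALSE)
    pairs <- pairs[sample(length(pairs), min(nEdges, length(pairs)))]
    ed <- do.call(rbind, lapply(pairs, function(p) data.frame(
        gene_a = nd$gene[p[1]], type_a = nd$cell_type[p[1]],
        gene_b = nd$gene[p[2]], type_b = nd$cell_type[p[2]],
        stringsAsFactors = FALSE)))
    MCTCNetwork(id, ed)
}

# plain queue BFS distances over an edge data.frame, by node label
bfsDistances <- function(ed, from) {
    a <- nodeKeyT(ed$gene_a, ed$type_a)
    b <- nodeKeyT(ed$gene_b, ed$type_b)
    nodes <- unique(c(a, b))
    dist <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
    if (!from %in% nodes) return(dist)
    dist[from] <- 0L
    queue <- from
    while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nb <- c(b[a == v], a[b == v])
        new <- nb[is.na(dist[nb])]
        dist[new] <- dist[v] + 1L
        queue <- c(queue, new)
    }
    dist
}

# exact one-sided Fisher p by enumerating all placements of the
# pattern-positive samples given the margins
fisherEnumOracle <- function(patternCol, driverCol) {
    n <- length(driverCol)
    cplus <- sum(patternCol)
    a <- sum(patternCol == 1 & driverCol == 1)
    if (cplus == 0) return(1)
    placements <- utils::combn(n, cplus, simplify = FALSE)
    overlaps <- vapply(placements, function(s) sum(driverCol[s]), 0)
    mean(overlaps >= a)
}

# minimal cohort with prescribed per-patient cell counts; expression is a
# small strictly positive matrix so nothing gets filtered away
makeCountsCohort <- function(cellCounts, drivers = NULL, nGenes = 4,
                             seed = 42) {
    stopifnot(is.matrix(cellCounts))
    pats <- rownames(cellCounts); types <- colnames(cellCounts)
    meta <- do.call(rbind, lapply(pats, function(p) {
        do.call(rbind, lapply(types, function(t) {
            n <- cellCounts[p, t]
            if (n == 0) return(NULL)
            data.frame(cell_id = sprintf("%s_%s_%03d", p, t, seq_len(n)),
                       patient_id = p, cell_type = t,
                       stringsAsFactors = FALSE)
        }))
    }))
    meta$cell_type <- factor(meta$cell_type, levels = types)
    expr <- withr::with_seed(seed,
        matrix(rpois(nGenes * nrow(meta), 3) + 1, nGenes, nrow(meta),
               dimnames = list(paste0("G", seq_len(nGenes)),
                               meta$cell_id)))
    if (is.null(drivers))
        drivers <- matrix(rep(c(1, 0), length.out = length(pats)),
                          ncol = 1, dimnames = list(pats, "DRV"))
    AnnotatedCohort(expr, meta, drivers)
}
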