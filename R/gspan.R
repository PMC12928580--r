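# Frequent connected subnetwork mining over MCTC networks.
#
# Pattern growth with exact support: every frequent pattern is extended by
# one edge through all of its embeddings in its supporting graphs, and
# candidates are de-duplicated by their canonical minimum DFS code. Because
# a candidate embeds in a graph exactly when one of its parent embeddings
# extends there, the accumulated graph set is the exact support set, and
# the search enumerates precisely the connected, isomorphism-distinct
# subgraphs above the support threshold (the gSpan pattern space).

KIND_LEVELS <- c("intracellular", "intercellular")

# convert networks to mgraphs over a shared node-label dictionary
networksToMgraphs <- function(networks) {
    labs <- sort(unique(unlist(lapply(networks, function(n) {
        nd <- netNodes(n)
        nodeKey(nd$gene, nd$cell_type)
    }))))
    graphs <- lapply(networks, function(n) {
        nd <- netNodes(n)
        keys <- nodeKey(nd$gene, nd$cell_type)
        ed <- netEdges(n)
        if (nrow(ed)) {
            u <- match(nodeKey(ed$gene_a, ed$type_a), keys)
            v <- match(nodeKey(ed$gene_b, ed$type_b), keys)
            el <- match(ed$kind, KIND_LEVELS)
            edges <- cbind(u, v, el)
        } else edges <- matrix(integer(), 0L, 3L)
        mgraph(match(keys, labs), edges)
    })
    list(graphs = graphs, labels = labs)
}

mgraphToPattern <- function(g, labels, patternId, code, support) {
    nd <- splitNodeKey(labels[g$labels])
    ed <- if (nrow(g$edges)) {
        data.frame(gene_a = nd$gene[g$edges[, 1L]],
                   type_a = nd$cell_type[g$edges[, 1L]],
                   gene_b = nd$gene[g$edges[, 2L]],
                   type_b = nd$cell_type[g$edges[, 2L]],
                   kind = KIND_LEVELS[g$edges[, 3L]],
                   stringsAsFactors = FALSE)
    } else emptyEdges()
    new("FrequentSubnetwork", patternId = as.integer(patternId),
        canonicalCode = code, nodes = nd, edges = ed,
        supportSet = support)
}

#' Mine frequent connected subnetworks (gSpan-style)
#'
#' Finds every connected labeled subgraph with at most \code{maxEdges}
#' edges that occurs (by label-preserving, not necessarily induced,
#' subgraph isomorphism) in at least \code{minSupport} of the input
#' networks, with its exact support set. Node labels are "gene@celltype"
#' and edge labels the intracellular/intercellular kind. Patterns are grown
#' edge-by-edge from their embeddings and canonicalized by minimum DFS
#' code, so the result is independent of input order. Single-node patterns
#' are excluded: candidate communication signatures are interactions.
#'
#' @param networks list of \linkS4class{MCTCNetwork} with unique sample
#'   ids.
#' @param minSupport minimum number of supporting networks (>= 2).
#' @param maxEdges largest pattern size in edges (default 5).
#' @return list of \linkS4class{FrequentSubnetwork}, ordered by canonical
#'   code, pattern ids 1..n in that order.
#' @seealso [encodeOccurrence()], [chooseSupport()]
#' @export
gspanMine <- function(networks, minSupport, maxEdges = 5L) {
    if (!length(networks)) stop("empty network list")
    if (minSupport < 2L) stop("minSupport must be >= 2")
    if (maxEdges < 1L) stop("maxEdges must be >= 1")
    ids <- vapply(networks, sampleId, "")
    if (anyDuplicated(ids)) stop("duplicate sample ids in network list")
    conv <- networksToMgraphs(networks)
    graphs <- conv$graphs
    nG <- length(graphs)

    # level 1: distinct labeled edges and their supporting graphs
    lvl <- new.env(parent = emptyenv())
    for (gi in seq_len(nG)) {
        g <- graphs[[gi]]
        if (!nrow(g$edges)) next
        la <- g$labels[g$edges[, 1L]]; lb <- g$labels[g$edges[, 2L]]
        key <- paste(pmin(la, lb), pmax(la, lb), g$edges[, 3L], sep = "_")
        for (k in unique(key)) {
            e <- which(key == k)[1L]
            ent <- if (is.null(lvl[[k]])) {
                u <- g$edges[e, 1L]; v <- g$edges[e, 2L]
                pat <- mgraph(sort(c(g$labels[u], g$labels[v])),
                              cbind(1L, 2L, g$edges[e, 3L]))
                list(pat = pat, graphs = integer())
            } else lvl[[k]]
            ent$graphs <- c(ent$graphs, gi)
            lvl[[k]] <- ent
        }
    }
    results <- list()
    seen <- new.env(parent = emptyenv())
    queue <- list()
    for (k in ls(lvl)) {
        ent <- lvl[[k]]
        code <- minDFSCodeString(ent$pat)
        seen[[code]] <- TRUE
        if (length(ent$graphs) >= minSupport)
            queue[[length(queue) + 1L]] <-
                list(pat = ent$pat, code = code, graphs = ent$graphs)
    }
    while (length(queue)) {
        cur <- queue[[1L]]; queue <- queue[-1L]
        results[[length(results) + 1L]] <- cur
        if (nrow(cur$pat$edges) >= maxEdges) next
        cands <- new.env(parent = emptyenv())
        for (gi in cur$graphs) {
            g <- graphs[[gi]]
            embs <- findEmbeddings(cur$pat, g)
            gadjEdges <- g$edges
            for (map in embs) {
                img <- map                      # pattern node -> graph node
                inImg <- match(seq_along(g$labels), img)  # graph -> pattern
                for (e in seq_len(nrow(gadjEdges))) {
                    u <- gadjEdges[e, 1L]; v <- gadjEdges[e, 2L]
                    el <- gadjEdges[e, 3L]
                    pu <- inImg[u]; pv <- inImg[v]
                    if (!is.na(pu) && !is.na(pv)) {
                        # backward: both endpoints mapped, edge not in pattern
                        dup <- any((cur$pat$edges[, 1L] == pu &
                                    cur$pat$edges[, 2L] == pv) |
                                   (cur$pat$edges[, 1L] == pv &
                                    cur$pat$edges[, 2L] == pu))
                        if (dup) next
                        newPat <- mgraph(cur$pat$labels,
                                         rbind(cur$pat$edges,
                                               c(pu, pv, el)))
                    } else if (!is.na(pu) || !is.na(pv)) {
                        # forward: grow one new labeled node
                        anchor <- if (is.na(pu)) pv else pu
                        newNode <- if (is.na(pu)) u else v
                        newPat <- mgraph(c(cur$pat$labels,
                                           g$labels[newNode]),
                                         rbind(cur$pat$edges,
                                               c(anchor,
                                                 length(cur$pat$labels) + 1L,
                                                 el)))
                    } else next
                    code <- minDFSCodeString(newPat)
                    ent <- cands[[code]]
                    if (is.null(ent))
                        ent <- list(pat = newPat, graphs = integer())
                    if (!gi %in% ent$graphs)
                        ent$graphs <- c(ent$graphs, gi)
                    cands[[code]] <- ent
                }
            }
        }
        for (code in ls(cands)) {
            if (!is.null(seen[[code]])) next
            seen[[code]] <- TRUE
            ent <- cands[[code]]
            if (length(ent$graphs) >= minSupport)
                queue[[length(queue) + 1L]] <-
                    list(pat = ent$pat, code = code, graphs = ent$graphs)
        }
    }
    ord <- order(vapply(results, function(r) r$code, ""))
    results <- results[ord]
    lapply(seq_along(results), function(i) {
        r <- results[[i]]
        mgraphToPattern(r$pat, conv$labels, i, r$code,
                        sort(ids[r$graphs]))
    })
}

#' One-hot occurrence matrix of mined patterns
#'
#' @param patterns list of \linkS4class{FrequentSubnetwork} mined from
#'   \code{networks}.
#' @param networks the same network list the patterns were mined from.
#' @return An \linkS4class{OccurrenceMatrix}: rows = samples, columns =
#'   pattern ids; entry 1 when the sample's network contains the pattern.
#' @export
encodeOccurrence <- function(patterns, networks) {
    ids <- vapply(networks, sampleId, "")
    if (anyDuplicated(ids)) stop("duplicate sample ids in network list")
    m <- matrix(0L, length(ids), length(patterns),
                dimnames = list(ids,
                    vapply(patterns, function(p)
                        as.character(p@patternId), "")))
    for (p in patterns) {
        unknown <- setdiff(p@supportSet, ids)
        if (length(unknown))
            stop("pattern ", p@patternId, " supported by unknown sample(s): ",
                 paste(unknown, collapse = ", "))
        m[p@supportSet, as.character(p@patternId)] <- 1L
    }
    new("OccurrenceMatrix", mat = m)
}

#' Suggest a support threshold from driver prevalence
#'
#' Advisory helper: suggests \code{ceiling(prevalence * n)} supporting
#' samples, together with the number of distinct single-interaction
#' patterns that would pass it (a cheap size estimate of the mining
#' output).
#'
#' @param networks list of \linkS4class{MCTCNetwork}.
#' @param targetDriverPrevalence expected fraction of samples carrying the
#'   driver of interest, in (0, 1].
#' @return list with \code{suggestion} (integer support) and
#'   \code{edgePatternEstimate}.
#' @export
chooseSupport <- function(networks, targetDriverPrevalence) {
    stopifnot(targetDriverPrevalence > 0, targetDriverPrevalence <= 1)
    n <- length(networks)
    sug <- as.integer(ceiling(targetDriverPrevalence * n))
    tabs <- lapply(networks, function(net) unique(edgeKey(netEdges(net))))
    counts <- table(unlist(tabs))
    list(suggestion = sug,
         edgePatternEstimate = sum(counts >= max(sug, 1L)))
}

#' Human-readable signature notation
#'
#' Formats a pattern's interactions as "GENE(TYPE) - GENE(TYPE)" strings
#' joined by "; ".
#'
#' @param pattern a \linkS4class{FrequentSubnetwork}.
#' @return character scalar.
#' @export
signatureNotation <- function(pattern) {
    ed <- netEdges(pattern)
    if (!nrow(ed)) return(sprintf("%s(%s)", pattern@nodes$gene[1],
                                  pattern@nodes$cell_type[1]))
    paste(sprintf("%s(%s) - %s(%s)", ed$gene_a, ed$type_a, ed$gene_b,
                  ed$type_b), collapse = "; ")
}

#' Export mined patterns as a TSV table
#'
#' @param patterns list of \linkS4class{FrequentSubnetwork}.
#' @param path output TSV.
#' @return Invisibly, the written data.frame (pattern_id, canonical_code,
#'   n_nodes, n_edges, signature, support, support_set).
#' @export
writePatterns <- function(patterns, path) {
    df <- data.frame(
        pattern_id = vapply(patterns, function(p) p@patternId, 0L),
        canonical_code = vapply(patterns, canonicalCode, ""),
        n_nodes = vapply(patterns, function(p) nrow(p@nodes), 0L),
        n_edges = vapply(patterns, function(p) nrow(p@edges), 0L),
        signature = vapply(patterns, signatureNotation, ""),
        support = vapply(patterns, function(p) length(p@supportSet), 0L),
        support_set = vapply(patterns, function(p)
            paste(p@supportSet, collapse = ","), ""),
        stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(df)
}
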