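# Label-preserving subgraph isomorphism on mgraphs (node-injective,
# non-induced): every pattern node maps to a distinct graph node with the
# same label and every pattern edge to a graph edge with the same edge
# label. Used for embedding enumeration during mining and for containment
# re-checks.

# order pattern nodes so each after the first touches an earlier one
patternSearchOrder <- function(p) {
    n <- length(p$labels)
    if (n == 1L) return(1L)
    adj <- mgraphAdjacency(p)
    order <- 1L
    seen <- rep(FALSE, n); seen[1L] <- TRUE
    while (length(order) < n) {
        nxt <- NA_integer_
        for (v in order) {
            nb <- adj[[v]][, 1L]
            cand <- nb[!seen[nb]]
            if (length(cand)) { nxt <- cand[1L]; break }
        }
        if (is.na(nxt)) stop("pattern is not connected")
        seen[nxt] <- TRUE
        order <- c(order, nxt)
    }
    order
}

# all embeddings (list of integer maps pattern node -> graph node), or just
# the first when firstOnly
findEmbeddings <- function(p, g, firstOnly = FALSE) {
    ord <- patternSearchOrder(p)
    padj <- mgraphAdjacency(p)
    gadj <- mgraphAdjacency(g)
    res <- list()
    n <- length(p$labels)
    assign1 <- function(pos, map) {
        if (!is.null(res$stop)) return(invisible())
        if (pos > n) {
            res[[length(res) + 1L]] <<- map
            if (firstOnly) res$stop <<- TRUE
            return(invisible())
        }
        pv <- ord[pos]
        prev <- ord[seq_len(pos - 1L)]
        # pattern edges from pv to already-mapped nodes
        need <- padj[[pv]]
        need <- need[need[, 1L] %in% prev, , drop = FALSE]
        anchor <- need[1L, ]                     # exists by search order
        ganchor <- gadj[[map[anchor[1L]]]]
        if (is.null(ganchor)) return(invisible())
        cand <- ganchor[ganchor[, 2L] == anchor[2L], 1L]
        cand <- cand[g$labels[cand] == p$labels[pv]]
        cand <- setdiff(cand, map[prev])
        for (gv in cand) {
            ok <- TRUE
            if (nrow(need) > 1L) for (k in 2L:nrow(need)) {
                gw <- map[need[k, 1L]]
                hit <- any(gadj[[gv]][, 1L] == gw &
                           gadj[[gv]][, 2L] == need[k, 2L])
                if (!hit) { ok <- FALSE; break }
            }
            if (!ok) next
            m2 <- map; m2[pv] <- gv
            assign1(pos + 1L, m2)
        }
    }
    roots <- which(g$labels == p$labels[ord[1L]])
    for (gv in roots) {
        map <- rep(NA_integer_, n)
        map[ord[1L]] <- gv
        if (n == 1L) { res[[length(res) + 1L]] <- map
                       if (firstOnly) break }
        else assign1(2L, map)
        if (!is.null(res$stop)) break
    }
    res$stop <- NULL
    res
}

containsMgraph <- function(g, p) length(findEmbeddings(p, g, TRUE)) > 0L
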