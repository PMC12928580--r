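# Canonical (minimum) DFS codes for small undirected labeled graphs.
#
# Internal representation ("mgraph"): list(labels = integer vector of node
# labels, edges = integer matrix with columns u, v, el). A DFS code is a
# sequence of edge tuples (i, j, l_i, l_e, l_j) over discovery indices;
# the minimum over all DFS traversals is a canonical form: two graphs get
# the same minimum code exactly when they are isomorphic with matching
# node and edge labels. Patterns here are tiny (a handful of edges), so a
# branch-and-bound enumeration of DFS traversals is ample.

mgraph <- function(labels, edges) {
    edges <- matrix(as.integer(edges), ncol = 3L,
                    dimnames = list(NULL, c("u", "v", "el")))
    list(labels = as.integer(labels), edges = edges)
}

mgraphAdjacency <- function(g) {
    n <- length(g$labels)
    adj <- vector("list", n)
    if (nrow(g$edges)) for (e in seq_len(nrow(g$edges))) {
        u <- g$edges[e, 1L]; v <- g$edges[e, 2L]; el <- g$edges[e, 3L]
        adj[[u]] <- rbind(adj[[u]], c(v, el, e))
        adj[[v]] <- rbind(adj[[v]], c(u, el, e))
    }
    adj
}

# gSpan tuple order. At the first differing position of two DFS codes of
# one graph the structural cases below are the only possible ones; across
# graphs any consistent total order suffices for canonicalization.
cmpTuple <- function(a, b) {
    fa <- a[1L] < a[2L]; fb <- b[1L] < b[2L]
    if (fa != fb) return(if (fb) -1L else 1L)       # backward < forward
    if (fa) {                                       # both forward
        if (a[2L] != b[2L]) return(sign(a[2L] - b[2L]))
        if (a[1L] != b[1L]) return(sign(b[1L] - a[1L]))
    } else {                                        # both backward
        if (a[1L] != b[1L]) return(sign(a[1L] - b[1L]))
        if (a[2L] != b[2L]) return(sign(a[2L] - b[2L]))
    }
    for (k in 3:5) if (a[k] != b[k]) return(sign(a[k] - b[k]))
    0L
}

# compare code prefixes row by row; shorter prefix of equal rows is smaller
cmpCode <- function(c1, c2) {
    n <- min(nrow(c1), nrow(c2))
    for (i in seq_len(n)) {
        r <- cmpTuple(c1[i, ], c2[i, ])
        if (r != 0L) return(r)
    }
    sign(nrow(c1) - nrow(c2))
}

# Enumerate DFS traversals with branch-and-bound against the best code so
# far. State: map (graph node -> dfs id), order (dfs id -> graph node),
# rightmost path of dfs ids, used edge ids.
minDFSCode <- function(g) {
    ne <- nrow(g$edges)
    if (ne == 0L) {
        if (length(g$labels) != 1L)
            stop("edgeless patterns must be single nodes")
        return(matrix(c(0L, 0L, g$labels[1L], 0L, g$labels[1L]), 1L))
    }
    adj <- mgraphAdjacency(g)
    best <- NULL
    tuple <- function(di, dj, u, v, el)
        c(di, dj, g$labels[u], el, g$labels[v])
    recurse <- function(code, map, order, rmpath, used) {
        if (nrow(code) == ne) {
            if (is.null(best) || cmpCode(code, best) < 0L) best <<- code
            return(invisible())
        }
        tryEdge <- function(tup, newMap, newOrder, newRmpath, newUsed) {
            cand <- rbind(code, tup)
            if (!is.null(best) && cmpCode(cand, best) > 0L)
                return(invisible())
            recurse(cand, newMap, newOrder, newRmpath, newUsed)
        }
        vr <- order[length(order)]             # rightmost vertex (graph id)
        # backward: close an unused edge from the rightmost vertex
        for (k in seq_len(nrow(adj[[vr]]))) {
            w <- adj[[vr]][k, 1L]; el <- adj[[vr]][k, 2L]
            eid <- adj[[vr]][k, 3L]
            if (used[eid] || is.na(map[w])) next
            tryEdge(tuple(map[vr], map[w], vr, w, el),
                    map, order, rmpath,
                    { u2 <- used; u2[eid] <- TRUE; u2 })
        }
        # forward: grow a new vertex from a rightmost-path vertex
        for (p in rev(seq_along(rmpath))) {
            vp <- order[rmpath[p] + 1L]        # dfs id -> graph node
            for (k in seq_len(nrow(adj[[vp]]))) {
                w <- adj[[vp]][k, 1L]; el <- adj[[vp]][k, 2L]
                eid <- adj[[vp]][k, 3L]
                if (used[eid] || !is.na(map[w])) next
                newId <- length(order)
                m2 <- map; m2[w] <- newId
                u2 <- used; u2[eid] <- TRUE
                tryEdge(tuple(rmpath[p], newId, vp, w, el),
                        m2, c(order, w), c(rmpath[seq_len(p)], newId), u2)
            }
        }
    }
    for (e in seq_len(ne)) {
        u <- g$edges[e, 1L]; v <- g$edges[e, 2L]; el <- g$edges[e, 3L]
        for (start in list(c(u, v), c(v, u))) {
            map <- rep(NA_integer_, length(g$labels))
            map[start[1L]] <- 0L; map[start[2L]] <- 1L
            used <- rep(FALSE, ne); used[e] <- TRUE
            recurse(matrix(tuple(0L, 1L, start[1L], start[2L], el), 1L),
                    map, c(start[1L], start[2L]), c(0L, 1L), used)
        }
    }
    best
}

codeString <- function(code) {
    paste(apply(code, 1L, paste, collapse = ","), collapse = ";")
}

minDFSCodeString <- function(g) codeString(minDFSCode(g))
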