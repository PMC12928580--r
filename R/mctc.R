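#' Construct a multi-cell-type communication network
#'
#' @param sampleId sample identifier.
#' @param edges data.frame with columns gene_a, type_a, gene_b, type_b and
#'   optionally kind (inferred from type equality when absent). Duplicate
#'   undirected edges collapse to one.
#' @param nodes optional node table; defaults to the edge endpoints.
#' @return A validated \linkS4class{MCTCNetwork}.
#' @export
MCTCNetwork <- function(sampleId, edges = emptyEdges(), nodes = NULL) {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (nrow(edges)) {
        if (!"kind" %in% colnames(edges))
            edges$kind <- edgeKindFor(edges$type_a, edges$type_b)
        edges <- dedupEdges(edges[, c("gene_a", "type_a", "gene_b",
                                      "type_b", "kind")])
    } else edges <- emptyEdges()
    if (is.null(nodes)) {
        nodes <- if (nrow(edges)) nodesFromEdges(edges) else emptyNodes()
    } else {
        nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
        nodes <- nodes[!duplicated(nodeKey(nodes$gene, nodes$cell_type)), ,
                       drop = FALSE]
        rownames(nodes) <- NULL
    }
    new("MCTCNetwork", sampleId = as.character(sampleId), nodes = nodes,
        edges = edges, info = list())
}

#' Read a communication network from a TSV edge list
#'
#' Rows are \code{geneA typeA geneB typeB [kind] [extra...]}; any extra
#' columns (e.g. weights or prizes from an external backend) are discarded.
#' When the kind column is absent it is inferred from cell-type equality.
#'
#' @param path edge-list file (tab-separated, no header).
#' @param sampleId identifier to attach.
#' @return An \linkS4class{MCTCNetwork}.
#' @export
readNetwork <- function(path, sampleId) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    rows <- strsplit(lines, "\t", fixed = TRUE)
    parsed <- lapply(seq_along(rows), function(i) {
        f <- trimws(rows[[i]])
        if (length(f) < 4L || any(!nzchar(f[1:4])))
            stop("malformed network row at line ", i, " of ", path)
        kind <- if (length(f) >= 5L && f[5] %in%
                    c("intracellular", "intercellular")) f[5]
                else edgeKindFor(f[2], f[4])
        if (kind != edgeKindFor(f[2], f[4]))
            stop("edge kind '", kind, "' inconsistent with cell types at ",
                 "line ", i, " of ", path)
        data.frame(gene_a = f[1], type_a = f[2], gene_b = f[3],
                   type_b = f[4], kind = kind, stringsAsFactors = FALSE)
    })
    MCTCNetwork(sampleId, do.call(rbind, c(parsed, list(emptyEdges()))))
}

#' Write a network as a TSV edge list
#'
#' @param net an \linkS4class{MCTCNetwork}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeNetwork <- function(net, path) {
    utils::write.table(netEdges(net), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Lightweight pairwise signal-transduction network
#'
#' A simple expression-threshold backend for building the per-cell-type-pair
#' network of a pseudo-sample. An intercellular edge (L@typeA)-(R@typeB) is
#' added for every ligand-receptor pair whose ligand is expressed in at
#' least \code{exprFracThreshold} of the typeA cells and whose receptor
#' passes the same threshold in typeB (and symmetrically for typeB ->
#' typeA). Intracellular edges from the gene-interaction network are then
#' attached within each type, restricted to expressed, retained genes lying
#' within \code{hopRadius} interaction hops of the ligands/receptors in use.
#'
#' Genes must also pass the per-type retention mask recorded by
#' [filterLowExpressed()] when one is present.
#'
#' @param ps a \linkS4class{PseudoSample}.
#' @param cohort the source \linkS4class{AnnotatedCohort}.
#' @param lrTable ligand-receptor data.frame
#'   (see [readLigandReceptorTable()]).
#' @param intra intracellular edge data.frame
#'   (see [readIntracellularNetwork()]).
#' @param typeA,typeB the two distinct focal cell types.
#' @param exprFracThreshold expressing-cell fraction above which a gene
#'   counts as expressed (default 0.1).
#' @param hopRadius intracellular neighborhood radius (default 1).
#' @return An \linkS4class{MCTCNetwork} for the pair.
#' @export
litePairwiseNetwork <- function(ps, cohort, lrTable, intra, typeA, typeB,
                                exprFracThreshold = 0.1, hopRadius = 1L) {
    if (typeA == typeB) stop("typeA and typeB must differ")
    if (!nrow(lrTable)) stop("empty ligand-receptor table")
    mask <- retentionMask(cohort)
    expressed <- function(type) {
        m <- psExpression(cohort, ps, type)
        frac <- rowMeans(m > 0)
        ok <- frac >= exprFracThreshold
        if (!is.null(mask)) ok <- ok & mask[, type]
        rownames(m)[ok]
    }
    exprA <- expressed(typeA)
    exprB <- expressed(typeB)
    pick <- function(sender, senderGenes, receiver, receiverGenes) {
        hit <- lrTable$ligand %in% senderGenes &
               lrTable$receptor %in% receiverGenes
        if (!any(hit)) return(emptyEdges())
        data.frame(gene_a = lrTable$ligand[hit], type_a = sender,
                   gene_b = lrTable$receptor[hit], type_b = receiver,
                   kind = "intercellular", stringsAsFactors = FALSE)
    }
    inter <- rbind(pick(typeA, exprA, typeB, exprB),
                   pick(typeB, exprB, typeA, exprA))
    intraEdges <- emptyEdges()
    for (t in c(typeA, typeB)) {
        seeds <- unique(c(inter$gene_a[inter$type_a == t],
                          inter$gene_b[inter$type_b == t]))
        if (!length(seeds) || !nrow(intra)) next
        genes <- if (t == typeA) exprA else exprB
        keep <- intra$gene_a %in% genes & intra$gene_b %in% genes
        sub <- intra[keep, , drop = FALSE]
        if (!nrow(sub)) next
        ball <- seeds
        frontier <- seeds
        for (h in seq_len(hopRadius)) {
            nb <- c(sub$gene_b[sub$gene_a %in% frontier],
                    sub$gene_a[sub$gene_b %in% frontier])
            frontier <- setdiff(unique(nb), ball)
            if (!length(frontier)) break
            ball <- c(ball, frontier)
        }
        inBall <- sub$gene_a %in% ball & sub$gene_b %in% ball
        if (any(inBall))
            intraEdges <- rbind(intraEdges, data.frame(
                gene_a = sub$gene_a[inBall], type_a = t,
                gene_b = sub$gene_b[inBall], type_b = t,
                kind = "intracellular", stringsAsFactors = FALSE))
    }
    MCTCNetwork(sampleId(ps), rbind(inter, intraEdges))
}

#' Union of pairwise networks into one MCTC network
#'
#' Node and edge sets are unioned with set semantics (shared edges counted
#' once); all inputs must belong to the same sample and a same edge tagged
#' with conflicting kinds is an error.
#'
#' @param nets list of \linkS4class{MCTCNetwork} sharing one sample id.
#' @param sampleIdOut optional identifier for the result (defaults to the
#'   shared input id).
#' @return The union \linkS4class{MCTCNetwork}.
#' @export
unionNetworks <- function(nets, sampleIdOut = NULL) {
    if (!length(nets)) stop("no networks to union")
    ids <- unique(vapply(nets, sampleId, ""))
    if (length(ids) > 1L)
        stop("networks belong to different samples: ",
             paste(ids, collapse = ", "))
    ed <- do.call(rbind, lapply(nets, netEdges))
    key <- edgeKey(ed)
    if (nrow(ed)) {
        kinds <- tapply(ed$kind, key, function(k) length(unique(k)))
        if (any(kinds > 1L))
            stop("same edge tagged with conflicting kinds: ",
                 paste(names(kinds)[kinds > 1L], collapse = ", "))
    }
    nd <- do.call(rbind, lapply(nets, netNodes))
    MCTCNetwork(if (is.null(sampleIdOut)) ids else sampleIdOut,
                dedupEdges(ed), nodes = nd)
}

#' Build one MCTC network per pseudo-sample with the lite backend
#'
#' For each pseudo-sample, a pairwise network is built for every unordered
#' pair of focal cell types and the pairwise networks are unioned.
#'
#' @inheritParams litePairwiseNetwork
#' @param psList list of \linkS4class{PseudoSample}.
#' @param focalTypes focal cell types (>= 2).
#' @return Named list of \linkS4class{MCTCNetwork}, one per pseudo-sample.
#' @export
mctcFromPseudosamples <- function(psList, cohort, lrTable, intra,
                                  focalTypes, exprFracThreshold = 0.1,
                                  hopRadius = 1L) {
    stopifnot(length(focalTypes) >= 2L)
    pairs <- utils::combn(focalTypes, 2L, simplify = FALSE)
    nets <- lapply(psList, function(ps) {
        pieces <- lapply(pairs, function(p)
            litePairwiseNetwork(ps, cohort, lrTable, intra, p[1], p[2],
                                exprFracThreshold, hopRadius))
        unionNetworks(pieces)
    })
    names(nets) <- vapply(psList, sampleId, "")
    nets
}

#' Convert a network to an igraph object
#'
#' Vertex names are "gene@celltype" labels; vertex attributes gene and
#' cell_type and the edge attribute kind are carried over.
#'
#' @param net an \linkS4class{MCTCNetwork}.
#' @return An undirected \code{igraph} graph.
#' @export
asIgraph <- function(net) {
    nd <- netNodes(net)
    ed <- netEdges(net)
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, nrow(nd),
                              name = nodeKey(nd$gene, nd$cell_type),
                              gene = nd$gene, cell_type = nd$cell_type)
    if (nrow(ed)) {
        from <- nodeKey(ed$gene_a, ed$type_a)
        to <- nodeKey(ed$gene_b, ed$type_b)
        g <- igraph::add_edges(g, rbind(from, to), kind = ed$kind)
    }
    g
}
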