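#' Expand an MCTC network until it contains the driver gene
#'
#' The communication network is centered on ligand-receptor pairs, so a
#' cancer driver gene need not be one of its nodes. Starting from the
#' network's nodes in the driver's cell type, breadth-first rounds add
#' first-order neighbors from the intracellular gene-interaction network
#' (as intracellular edges within that cell type) and stop at the first
#' round in which the (driver, cancer cell type) node appears. With
#' \code{allTypes = TRUE} the expansion runs within every cell type, though
#' only the driver's own type can satisfy the stopping rule.
#'
#' @param net an \linkS4class{MCTCNetwork}.
#' @param driver driver gene symbol.
#' @param cancerType the cancer cell type hosting the driver.
#' @param intra intracellular edge data.frame
#'   (see [readIntracellularNetwork()]).
#' @param maxRounds cap on expansion rounds (default 6); if the driver is
#'   not reached the fully expanded network is returned and flagged.
#' @param allTypes expand within all cell types instead of only the
#'   driver's (default \code{FALSE}).
#' @return The expanded \linkS4class{MCTCNetwork}; its \code{info} list
#'   records \code{rounds} (stopping round) and \code{reached}.
#' @export
expandToDriver <- function(net, driver, cancerType, intra, maxRounds = 6L,
                           allTypes = FALSE) {
    if (maxRounds < 1L) stop("maxRounds must be >= 1")
    intraGenes <- unique(c(intra$gene_a, intra$gene_b))
    if (!driver %in% intraGenes)
        stop("driver gene '", driver,
             "' is absent from the intracellular network")
    nd <- netNodes(net)
    types <- if (allTypes) unique(nd$cell_type) else cancerType
    geneSets <- lapply(stats::setNames(types, types), function(t)
        unique(nd$gene[nd$cell_type == t]))
    reached <- driver %in% geneSets[[cancerType]]
    rounds <- 0L
    if (reached) {
        out <- net
        out@info <- list(rounds = 0L, reached = TRUE, driver = driver,
                         cancer_type = cancerType)
        return(out)
    }
    neighborsOf <- function(genes)
        unique(c(intra$gene_b[intra$gene_a %in% genes],
                 intra$gene_a[intra$gene_b %in% genes]))
    while (!reached && rounds < maxRounds) {
        grew <- FALSE
        for (t in types) {
            add <- setdiff(neighborsOf(geneSets[[t]]), geneSets[[t]])
            if (length(add)) {
                geneSets[[t]] <- c(geneSets[[t]], add)
                grew <- TRUE
            }
        }
        rounds <- rounds + 1L
        reached <- driver %in% geneSets[[cancerType]]
        if (!grew) break
    }
    newIntra <- do.call(rbind, lapply(types, function(t) {
        genes <- geneSets[[t]]
        hit <- intra$gene_a %in% genes & intra$gene_b %in% genes
        if (!any(hit)) return(emptyEdges())
        data.frame(gene_a = intra$gene_a[hit], type_a = t,
                   gene_b = intra$gene_b[hit], type_b = t,
                   kind = "intracellular", stringsAsFactors = FALSE)
    }))
    allNodes <- rbind(nd, do.call(rbind, lapply(types, function(t) {
        if (!length(geneSets[[t]])) return(emptyNodes())
        data.frame(gene = geneSets[[t]], cell_type = t,
                   stringsAsFactors = FALSE)
    })))
    out <- MCTCNetwork(sampleId(net), rbind(netEdges(net), newIntra),
                       nodes = allNodes)
    out@info <- list(rounds = rounds, reached = reached,
                     driver = driver, cancer_type = cancerType)
    if (!reached)
        warning("driver '", driver, "' not reached within ", maxRounds,
                " expansion rounds")
    out
}

#' Shortest intrinsic-extrinsic paths from a driver to a signature
#'
#' For each node of the signature present in the expanded network, returns
#' the shortest unweighted path(s) from the driver node. With
#' \code{mode = "all_shortest"} every minimal path is returned; with
#' \code{mode = "one"} only the lexicographically smallest node-label
#' sequence among the minimal paths. Signature nodes absent from or
#' unreachable in the network yield an empty-path entry with a warning.
#'
#' @param expanded an expanded \linkS4class{MCTCNetwork}
#'   (see [expandToDriver()]).
#' @param driverNode "gene@celltype" label of the driver node.
#' @param signature a \linkS4class{FrequentSubnetwork} (or a data.frame of
#'   nodes with gene/cell_type columns).
#' @param mode \code{"all_shortest"} (default) or \code{"one"}.
#' @return list of \linkS4class{IEPath}.
#' @export
iePaths <- function(expanded, driverNode,
                    signature, mode = c("all_shortest", "one")) {
    mode <- match.arg(mode)
    g <- asIgraph(expanded)
    if (!driverNode %in% igraph::V(g)$name)
        stop("driver node ", driverNode, " is not in the expanded network")
    sigNodes <- if (is(signature, "FrequentSubnetwork"))
        netNodes(signature) else as.data.frame(signature)
    targets <- unique(nodeKey(sigNodes$gene, sigNodes$cell_type))
    out <- list()
    for (tg in targets) {
        if (!tg %in% igraph::V(g)$name) {
            warning("signature node ", tg,
                    " absent from the expanded network")
            out[[length(out) + 1L]] <- new("IEPath",
                driverNode = driverNode, targetNode = tg,
                nodes = character(), length = NA_integer_)
            next
        }
        sp <- suppressWarnings(
            igraph::all_shortest_paths(g, from = driverNode, to = tg))
        paths <- sp$vpaths
        if (!length(paths)) {
            warning("signature node ", tg, " unreachable from ",
                    driverNode)
            out[[length(out) + 1L]] <- new("IEPath",
                driverNode = driverNode, targetNode = tg,
                nodes = character(), length = NA_integer_)
            next
        }
        labs <- lapply(paths, function(p) igraph::V(g)$name[as.integer(p)])
        if (mode == "one") {
            keys <- vapply(labs, paste, "", collapse = "\r")
            labs <- labs[order(keys)[1L]]
        }
        for (nodes in labs)
            out[[length(out) + 1L]] <- new("IEPath",
                driverNode = driverNode, targetNode = tg, nodes = nodes,
                length = length(nodes) - 1L)
    }
    out
}

#' Minimal distance from the driver to any signature node
#'
#' @param paths list of \linkS4class{IEPath} from [iePaths()].
#' @return integer, the minimum path length (NA if nothing reachable).
#' @export
signatureDistance <- function(paths) {
    lens <- vapply(paths, function(p) p@length, NA_integer_)
    if (all(is.na(lens))) NA_integer_ else min(lens, na.rm = TRUE)
}

#' Export intrinsic-extrinsic paths for visualization
#'
#' Writes the union of the given paths as a subnetwork. SIF rows are
#' "node <kind> node"; GraphML carries gene, cell_type and on-signature
#' node attributes (readable back with igraph); TSV is a plain edge list.
#' Overlapping path edges are de-duplicated. An empty path list yields an
#' empty but valid file.
#'
#' @param paths list of \linkS4class{IEPath}.
#' @param path output file.
#' @param fmt one of "sif", "graphml", "tsv".
#' @param signatureNodes optional character vector of "gene@celltype"
#'   labels flagged as on-signature in the export.
#' @return Invisibly, \code{path}.
#' @export
exportIE <- function(paths, path, fmt = c("sif", "graphml", "tsv"),
                     signatureNodes = character()) {
    fmt <- match.arg(fmt)
    edges <- list()
    for (p in paths) {
        nn <- p@nodes
        if (length(nn) < 2L) next
        for (i in seq_len(length(nn) - 1L))
            edges[[length(edges) + 1L]] <- c(nn[i], nn[i + 1L])
    }
    em <- if (length(edges)) unique(t(vapply(edges, function(e)
        c(pmin(e[1], e[2]), pmax(e[1], e[2])), character(2L))))
        else matrix(character(), 0L, 2L)
    aDf <- splitNodeKey(em[, 1L]); bDf <- splitNodeKey(em[, 2L])
    kind <- if (nrow(em)) edgeKindFor(aDf$cell_type, bDf$cell_type)
            else character()
    if (fmt == "sif") {
        writeLines(if (nrow(em))
            paste(em[, 1L], kind, em[, 2L], sep = "\t") else character(),
            path)
    } else if (fmt == "tsv") {
        utils::write.table(
            data.frame(gene_a = aDf$gene, type_a = aDf$cell_type,
                       gene_b = bDf$gene, type_b = bDf$cell_type,
                       kind = kind),
            path, sep = "\t", quote = FALSE, row.names = FALSE,
            col.names = FALSE)
    } else {
        nodes <- unique(c(em[, 1L], em[, 2L],
                          unlist(lapply(paths, function(p) p@nodes))))
        nd <- splitNodeKey(nodes)
        g <- igraph::make_empty_graph(0, directed = FALSE)
        g <- igraph::add_vertices(g, length(nodes), name = nodes,
                                  gene = nd$gene, cell_type = nd$cell_type,
                                  on_signature = nodes %in% signatureNodes)
        if (nrow(em))
            g <- igraph::add_edges(g, rbind(em[, 1L], em[, 2L]),
                                   kind = kind)
        igraph::write_graph(g, path, format = "graphml")
    }
    invisible(path)
}
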