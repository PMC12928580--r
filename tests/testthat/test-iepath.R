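chainIntra <- function(...) {
    genes <- c(...)
    data.frame(gene_a = genes[-length(genes)], gene_b = genes[-1],
               stringsAsFactors = FALSE)
}

baseNet <- function() MCTCNetwork("s1", data.frame(
    gene_a = c("L", "R"), type_a = c("TC", "Mph"),
    gene_b = c("R", "X"), type_b = c("Mph", "Mph")))

test_that("driver expansion stops at the minimal BFS round", {
    net <- baseNet()
    # driver already present: nothing changes
    intra <- chainIntra("L", "Q")
    netL <- MCTCNetwork("s1", data.frame(
        gene_a = "L", type_a = "TC", gene_b = "R", type_b = "Mph"))
    ex0 <- expandToDriver(netL, "L", "TC", intra)
    expect_identical(ex0@info$rounds, 0L)
    expect_identical(netEdges(ex0), netEdges(netL))
    # driver one intracellular hop away
    ex1 <- expandToDriver(netL, "Q", "TC", intra)
    expect_identical(ex1@info$rounds, 1L)
    expect_true("Q@TC" %in% nodeKeyT(netNodes(ex1)$gene,
                                     netNodes(ex1)$cell_type))
    # chain driver-x-y with y in the network: reached at round 2, and the
    # added node set equals the radius-2 BFS ball in the intra network
    intra2 <- chainIntra("D", "x", "L")
    ex2 <- expandToDriver(netL, "D", "TC", intra2)
    expect_identical(ex2@info$rounds, 2L)
    expect_setequal(netNodes(ex2)$gene[netNodes(ex2)$cell_type == "TC"],
                    c("L", "x", "D"))
    # driver missing from the intracellular universe
    expect_error(expandToDriver(netL, "ZZ", "TC", intra), "absent")
    # unreachable within maxRounds is flagged, not fatal
    intra3 <- rbind(chainIntra("D", "a", "b"), chainIntra("L", "c"))
    expect_warning(ex3 <- expandToDriver(netL, "D", "TC", intra3,
                                         maxRounds = 3), "not reached")
    expect_false(ex3@info$reached)
})

test_that("expansion is monotone across rounds", {
    withr::with_seed(8, {
        intra <- data.frame(gene_a = sample(paste0("g", 1:15), 25, TRUE),
                            gene_b = sample(paste0("g", 1:15), 25, TRUE))
        intra <- intra[intra$gene_a != intra$gene_b, ]
        net <- MCTCNetwork("s", data.frame(
            gene_a = "g1", type_a = "TC", gene_b = "g2", type_b = "Mph"))
        sets <- lapply(1:4, function(k)
            suppressWarnings(netNodes(expandToDriver(
                net, "g15", "TC", intra, maxRounds = k))))
        for (k in 2:4) {
            prev <- nodeKeyT(sets[[k - 1]]$gene, sets[[k - 1]]$cell_type)
            cur <- nodeKeyT(sets[[k]]$gene, sets[[k]]$cell_type)
            expect_true(all(prev %in% cur))
        }
    })
})

test_that("IE paths are shortest and all co-minimal routes are returned", {
    # driver adjacent to the signature ligand: length 1
    net <- baseNet()
    intra <- chainIntra("D", "L")
    ex <- expandToDriver(net, "D", "TC", intra)
    sig <- data.frame(gene = "L", cell_type = "TC")
    p <- iePaths(ex, "D@TC", sig)
    expect_length(p, 1L)
    expect_identical(p[[1]]@length, 1L)
    # two equal-length routes both returned in all_shortest mode
    diamond <- rbind(chainIntra("D", "a", "L"), chainIntra("D", "b", "L"))
    ex2 <- expandToDriver(net, "D", "TC", diamond)
    p2 <- iePaths(ex2, "D@TC", sig, mode = "all_shortest")
    expect_length(p2, 2L)
    expect_identical(sort(vapply(p2, function(x) x@nodes[2], "")),
                     c("a@TC", "b@TC"))
    p2one <- iePaths(ex2, "D@TC", sig, mode = "one")
    expect_length(p2one, 1L)
    expect_identical(p2one[[1]]@nodes[2], "a@TC")
    # absent signature node: empty path plus warning, not an error
    expect_warning(p3 <- iePaths(ex, "D@TC",
        data.frame(gene = "NOPE", cell_type = "CTL")), "absent")
    expect_identical(p3[[1]]@nodes, character())
    expect_true(is.na(p3[[1]]@length))
})

test_that("path lengths agree with a BFS oracle on random networks", {
    withr::with_seed(99, {
        for (i in 1:25) {
            net <- randomNetwork("s", nNodes = sample(6:10, 1),
                                 nEdges = sample(8:14, 1),
                                 genes = paste0("G", 1:6),
                                 types = c("T1", "T2"))
            ed <- netEdges(net)
            nodes <- nodeKeyT(netNodes(net)$gene, netNodes(net)$cell_type)
            from <- nodes[1]
            dist <- bfsDistances(ed, from)
            targets <- netNodes(net)[sample(nrow(netNodes(net)),
                                            min(3, nrow(netNodes(net)))), ]
            paths <- suppressWarnings(iePaths(net, from, targets))
            for (p in paths) {
                want <- dist[p@targetNode]
                if (is.na(want)) expect_identical(p@nodes, character())
                else expect_identical(p@length, unname(want))
            }
        }
    })
})

test_that("path export round-trips and de-duplicates overlapping edges", {
    p1 <- new("IEPath", driverNode = "D@TC", targetNode = "R@Mph",
              nodes = c("D@TC", "L@TC", "R@Mph"), length = 2L)
    p2 <- new("IEPath", driverNode = "D@TC", targetNode = "X@Mph",
              nodes = c("D@TC", "L@TC", "X@Mph"), length = 2L)
    dir <- withr::local_tempdir()
    sif <- file.path(dir, "p.sif")
    exportIE(list(p1), sif, "sif")
    expect_length(readLines(sif), 2L)       # 3 nodes -> 2 interactions
    exportIE(list(p1, p2), sif, "sif")
    expect_length(readLines(sif), 3L)       # shared D-L edge written once
    gml <- file.path(dir, "p.graphml")
    exportIE(list(p1, p2), gml, "graphml", signatureNodes = "R@Mph")
    g <- igraph::read_graph(gml, format = "graphml")
    expect_setequal(igraph::V(g)$name,
                    c("D@TC", "L@TC", "R@Mph", "X@Mph"))
    expect_equal(igraph::ecount(g), 3)
    expect_identical(igraph::V(g)$on_signature[
        igraph::V(g)$name == "R@Mph"], TRUE)
    # empty path list still writes a valid (empty) file
    exportIE(list(), sif, "sif")
    expect_length(readLines(sif), 0L)
})
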