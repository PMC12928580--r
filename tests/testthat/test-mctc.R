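test_that("edge-list networks read with set semantics and kind checks", {
    dir <- withr::local_tempdir()
    writeLines(c("L\tTC\tR\tMph", "R\tMph\tX\tMph"),
               file.path(dir, "net.tsv"))
    net <- readNetwork(file.path(dir, "net.tsv"), "s1")
    expect_identical(nrow(netNodes(net)), 3L)
    expect_identical(sort(netEdges(net)$kind),
                     c("intercellular", "intracellular"))
    # duplicate rows collapse; trailing weight columns are discarded
    writeLines(c("L\tTC\tR\tMph\tintercellular\t0.8",
                 "L\tTC\tR\tMph\tintercellular\t0.3"),
               file.path(dir, "dup.tsv"))
    expect_identical(nrow(netEdges(readNetwork(file.path(dir, "dup.tsv"),
                                               "s2"))), 1L)
    writeLines("A\tTC\tB\tTC\tintercellular", file.path(dir, "bad.tsv"))
    expect_error(readNetwork(file.path(dir, "bad.tsv"), "s3"),
                 "inconsistent")
    writeLines("A\tTC\tB", file.path(dir, "short.tsv"))
    expect_error(readNetwork(file.path(dir, "short.tsv"), "s4"), "line 1")
    # round trip
    writeNetwork(net, file.path(dir, "out.tsv"))
    net2 <- readNetwork(file.path(dir, "out.tsv"), "s1")
    expect_identical(netNodes(net2), netNodes(net))
    expect_setequal(cccmine:::edgeKey(netEdges(net2)),
                    cccmine:::edgeKey(netEdges(net)))
})

test_that("lite backend applies the threshold, symmetry and hop rules", {
    # hand-built pseudo-sample: L in 80% of TC, R in 60% of Mph, X in 100%
    expr <- matrix(0, 4, 20,
                   dimnames = list(c("L", "R", "X", "Z"),
                                   paste0("c", 1:20)))
    expr["L", 1:8] <- 1          # TC cells c1..c10
    expr["R", 11:16] <- 1        # Mph cells c11..c20
    expr["X", 11:20] <- 1
    expr["Z", 11] <- 1           # 10% of Mph: below 0.5 threshold
    meta <- data.frame(cell_id = colnames(expr), patient_id = "P1",
                       cell_type = rep(c("TC", "Mph"), each = 10))
    co <- AnnotatedCohort(expr, meta,
                          matrix(1, 1, 1, dimnames = list("P1", "DRV")))
    ps <- new("PseudoSample", sampleId = "P1_rep1", sourcePatient = "P1",
              replicateIndex = 1L,
              cellsByType = list(TC = paste0("c", 1:10),
                                 Mph = paste0("c", 11:20)),
              driverVector = c(DRV = 1))
    lr <- data.frame(ligand = c("L", "L"), receptor = c("R", "Z"))
    intra <- data.frame(gene_a = c("R", "X"), gene_b = c("X", "Z"))
    net <- litePairwiseNetwork(ps, co, lr, intra, "TC", "Mph",
                               exprFracThreshold = 0.5, hopRadius = 1)
    keys <- cccmine:::edgeKey(netEdges(net))
    expect_true("L@TC--R@Mph" %in% keys)          # 0.8 and 0.6 pass 0.5
    expect_false(any(grepl("Z@", keys)))          # Z below threshold
    expect_true("R@Mph--X@Mph" %in% keys)         # 1-hop intracellular
    # every intercellular edge corresponds to a ligand-receptor row
    inter <- netEdges(net)[netEdges(net)$kind == "intercellular", ]
    expect_true(all(paste(inter$gene_a, inter$gene_b) %in%
                    paste(lr$ligand, lr$receptor)))
    expect_error(litePairwiseNetwork(ps, co, lr[0, ], intra, "TC", "Mph"),
                 "empty")
    expect_error(litePairwiseNetwork(ps, co, lr, intra, "TC", "TC"),
                 "differ")
})

test_that("network union has set semantics and detects kind conflicts", {
    e1 <- data.frame(gene_a = c("A", "B", "C"), type_a = "T1",
                     gene_b = c("D", "E", "F"), type_b = "T2")
    e2 <- data.frame(gene_a = c("G", "H", "I"), type_a = "T1",
                     gene_b = c("J", "K", "L"), type_b = "T3")
    n1 <- MCTCNetwork("s", e1); n2 <- MCTCNetwork("s", e2)
    u <- unionNetworks(list(n1, n2))
    expect_identical(nrow(netEdges(u)), 6L)
    # shared edge counted once
    n3 <- MCTCNetwork("s", e1[1, ])
    expect_identical(nrow(netEdges(unionNetworks(list(n1, n3)))), 3L)
    # commutative / associative / idempotent over random networks
    withr::with_seed(5, {
        for (i in 1:10) {
            nets <- lapply(1:3, function(k)
                randomNetwork("s", nEdges = sample(3:6, 1)))
            key <- function(n) sort(cccmine:::edgeKey(netEdges(n)))
            ab <- unionNetworks(nets[1:2]); ba <- unionNetworks(nets[2:1])
            expect_identical(key(ab), key(ba))
            expect_identical(key(unionNetworks(list(ab, nets[[3]]))),
                             key(unionNetworks(list(nets[[1]],
                                 unionNetworks(nets[2:3])))))
            expect_identical(key(unionNetworks(list(nets[[1]],
                                                    nets[[1]]))),
                             key(nets[[1]]))
        }
    })
    expect_error(unionNetworks(list(n1, MCTCNetwork("other", e2))),
                 "different samples")
})

test_that("3-type union covers all pairwise networks", {
    co <- filterLowExpressed(simulateExpressionCohort(
        simConfig(nPatients = 4, cellsPerType = 30, seed = 21)))
    ps <- generatePseudosamples(co, c("TC", "Mph", "CTL"), minCells = 20,
                                seed = 2)
    lr <- data.frame(ligand = paste0("LIG", 1:6),
                     receptor = paste0("REC", 1:6))
    intra <- data.frame(gene_a = "REC3", gene_b = "TGT3")
    types <- c("TC", "Mph", "CTL")
    nets <- mctcFromPseudosamples(ps, co, lr, intra, types,
                                  exprFracThreshold = 0.5)
    pieces <- lapply(utils::combn(types, 2, simplify = FALSE), function(p)
        litePairwiseNetwork(ps[[1]], co, lr, intra, p[1], p[2],
                            exprFracThreshold = 0.5))
    manual <- sort(unique(unlist(lapply(pieces, function(n)
        cccmine:::edgeKey(netEdges(n))))))
    expect_identical(sort(cccmine:::edgeKey(netEdges(nets[[1]]))), manual)
    nodeKeys <- sort(unique(unlist(lapply(pieces, function(n)
        nodeKeyT(netNodes(n)$gene, netNodes(n)$cell_type)))))
    expect_identical(sort(nodeKeyT(netNodes(nets[[1]])$gene,
                                   netNodes(nets[[1]])$cell_type)),
                     nodeKeys)
})
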