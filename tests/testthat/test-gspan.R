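edgeDf <- function(ga, ta, gb, tb)
    data.frame(gene_a = ga, type_a = ta, gene_b = gb, type_b = tb,
               stringsAsFactors = FALSE)

test_that("single-edge patterns and support sets are mined exactly", {
    g <- function(id) MCTCNetwork(id, edgeDf("A", "TC", "B", "Mph"))
    pats <- gspanMine(list(g("s1"), g("s2"), g("s3")), minSupport = 2)
    expect_length(pats, 1L)
    expect_identical(supportSet(pats[[1]]), c("s1", "s2", "s3"))
    expect_identical(nrow(netEdges(pats[[1]])), 1L)
    # e1 in two graphs, e2 in one: only e1 survives min_support 2
    nets <- list(g("s1"), g("s2"),
                 MCTCNetwork("s3", edgeDf("C", "TC", "D", "Mph")),
                 MCTCNetwork("s4", edgeDf("E", "TC", "F", "CTL")))
    pats2 <- gspanMine(nets, minSupport = 2)
    expect_length(pats2, 1L)
    expect_identical(supportSet(pats2[[1]]), c("s1", "s2"))
    expect_error(gspanMine(list(), 2), "empty")
    expect_error(gspanMine(list(g("s1")), 1), "minSupport")
})

test_that("mined patterns and supports equal brute-force enumeration", {
    withr::with_seed(2024, {
        for (i in 1:12) {
            nets <- lapply(seq_len(sample(4:6, 1)), function(k)
                randomNetwork(paste0("s", k),
                              nNodes = sample(5:8, 1),
                              nEdges = sample(4:10, 1)))
            ms <- sample(2:3, 1)
            mined <- minedAsKeys(gspanMine(nets, ms, maxEdges = 3))
            brute <- bruteMine(nets, ms, maxEdges = 3)
            expect_identical(mined, brute)
        }
    })
})

test_that("pattern supports are anti-monotone in sub-patterns", {
    withr::with_seed(77, {
        nets <- lapply(1:6, function(k)
            randomNetwork(paste0("s", k), nNodes = 7, nEdges = 8))
        pats <- gspanMine(nets, 2, maxEdges = 4)
        keyed <- minedAsKeys(pats)
        for (p in pats) {
            ed <- netEdges(p)
            if (nrow(ed) < 2) next
            for (drop in seq_len(nrow(ed))) {
                sub <- ed[-drop, , drop = FALSE]
                if (!edgeSetConnected(sub)) next
                subSupport <- keyed[[edgeSetKeyT(sub)]]
                expect_true(length(supportSet(p)) <= length(subSupport))
                expect_true(all(supportSet(p) %in% subSupport))
            }
        }
    })
})

test_that("mining output is independent of input graph order", {
    withr::with_seed(31, {
        nets <- lapply(1:5, function(k)
            randomNetwork(paste0("s", k), nNodes = 6, nEdges = 7))
        a <- gspanMine(nets, 2, maxEdges = 3)
        b <- gspanMine(rev(nets), 2, maxEdges = 3)
        expect_identical(vapply(a, canonicalCode, ""),
                         vapply(b, canonicalCode, ""))
        expect_identical(lapply(a, supportSet), lapply(b, supportSet))
    })
})

test_that("raising the support threshold shrinks the pattern set", {
    withr::with_seed(13, {
        nets <- lapply(1:8, function(k)
            randomNetwork(paste0("s", k), nNodes = 6, nEdges = 6))
        codes <- lapply(2:4, function(ms)
            vapply(gspanMine(nets, ms, maxEdges = 3), canonicalCode, ""))
        expect_true(all(codes[[2]] %in% codes[[1]]))
        expect_true(all(codes[[3]] %in% codes[[2]]))
    })
})

test_that("canonical DFS codes are permutation-invariant and injective", {
    mg <- cccmine:::mgraph
    code <- cccmine:::minDFSCodeString
    # repeated node labels exercise real isomorphism: a labeled triangle
    # and a labeled path, under every node permutation
    tri <- list(labels = c(1L, 1L, 2L),
                edges = rbind(c(1L, 2L, 1L), c(2L, 3L, 1L),
                              c(1L, 3L, 2L)))
    path <- list(labels = c(1L, 1L, 2L),
                 edges = rbind(c(1L, 2L, 1L), c(2L, 3L, 1L)))
    permuted <- function(g, perm) {
        inv <- order(perm)
        mg(g$labels[perm],
           cbind(inv[g$edges[, 1]], inv[g$edges[, 2]], g$edges[, 3]))
    }
    perms <- list(1:3, c(2L, 1L, 3L), c(3L, 1L, 2L), c(1L, 3L, 2L),
                  c(2L, 3L, 1L), c(3L, 2L, 1L))
    triCodes <- vapply(perms, function(p)
        code(permuted(mg(tri$labels, tri$edges), p)), "")
    pathCodes <- vapply(perms, function(p)
        code(permuted(mg(path$labels, path$edges), p)), "")
    expect_length(unique(triCodes), 1L)
    expect_length(unique(pathCodes), 1L)
    expect_false(triCodes[1] == pathCodes[1])
    # different edge labels must separate otherwise identical graphs
    e1 <- mg(c(1L, 2L), cbind(1L, 2L, 1L))
    e2 <- mg(c(1L, 2L), cbind(1L, 2L, 2L))
    expect_false(code(e1) == code(e2))
})

test_that("occurrence matrix mirrors support sets and containment", {
    withr::with_seed(55, {
        nets <- lapply(1:6, function(k)
            randomNetwork(paste0("s", k), nNodes = 6, nEdges = 6))
        pats <- gspanMine(nets, 2, maxEdges = 3)
        F <- encodeOccurrence(pats, nets)
        m <- occurrence(F)
        expect_identical(rownames(m), vapply(nets, sampleId, ""))
        for (p in pats) {
            expect_identical(sum(m[, as.character(p@patternId)]),
                             length(supportSet(p)))
            # re-check containment independently: connected edge subsets
            pkey <- edgeSetKeyT(netEdges(p))
            for (i in seq_along(nets)) {
                inBrute <- pkey %in% names(bruteMine(nets[i], 1,
                                                     nrow(netEdges(p))))
                expect_identical(m[i, as.character(p@patternId)] == 1L,
                                 inBrute)
            }
        }
    })
    # zero patterns: matrix keeps the row index
    n1 <- MCTCNetwork("a", edgeDf("A", "T1", "B", "T2"))
    n2 <- MCTCNetwork("b", edgeDf("C", "T1", "D", "T2"))
    F0 <- encodeOccurrence(list(), list(n1, n2))
    expect_identical(dim(occurrence(F0)), c(2L, 0L))
})

test_that("support suggestion follows prevalence and is monotone", {
    nets <- lapply(1:50, function(k)
        MCTCNetwork(paste0("s", k), edgeDf("A", "TC", "B", "Mph")))
    expect_identical(chooseSupport(nets, 0.4)$suggestion, 20L)
    expect_identical(chooseSupport(nets[1:10], 0.1)$suggestion, 1L)
    sugg <- vapply(seq(0.05, 1, by = 0.05), function(pr)
        chooseSupport(nets, pr)$suggestion, 0L)
    expect_true(all(diff(sugg) >= 0))
    expect_identical(chooseSupport(nets, 0.4)$edgePatternEstimate, 1L)
})
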