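test_that("MHC-I score is the mean of the available core genes", {
    genes <- mhc1CoreSet()
    m <- matrix(5, length(genes), 3,
                dimnames = list(genes, paste0("s", 1:3)))
    expect_equal(unname(mhc1Score(m)), rep(5, 3))
    # permuting gene rows changes nothing
    withr::with_seed(3, {
        m2 <- matrix(rexp(length(genes) * 4), length(genes), 4,
                     dimnames = list(genes, paste0("s", 1:4)))
        expect_equal(mhc1Score(m2), mhc1Score(m2[sample(genes), ]))
        expect_equal(mhc1Score(m2), colMeans(m2))
    })
    expect_warning(s <- mhc1Score(m2[1:4, , drop = FALSE]), "missing")
    expect_equal(s, colMeans(m2[1:4, ]))
    expect_error(mhc1Score(m2[0, , drop = FALSE]), "none")
})

test_that("CYT score is the geometric mean of the effectors", {
    m <- matrix(c(4, 9), 2, 1, dimnames = list(c("GZMA", "PRF1"), "s1"))
    expect_equal(unname(cytScore(m, pseudocount = 0)), 6)
    m2 <- matrix(c(7, 7), 2, 1, dimnames = list(c("GZMA", "PRF1"), "s1"))
    expect_equal(unname(cytScore(m2, pseudocount = 0)), 7)
    withr::with_seed(11, {
        r <- matrix(rexp(40), 2, 20,
                    dimnames = list(c("GZMA", "PRF1"), paste0("s", 1:20)))
        cyt <- cytScore(r, pseudocount = 0)
        expect_true(all(cyt <= colMeans(r) + 1e-12))      # AM-GM
        expect_equal(cyt, cytScore(r[, 20:1],
            pseudocount = 0)[names(cyt)])             # order-invariant
    })
    expect_error(cytScore(matrix(1, 1, 1, dimnames = list("GZMA", "s"))),
                 "missing")
    expect_error(cytScore(matrix(c(-1, 2), 2, 1,
        dimnames = list(c("GZMA", "PRF1"), "s"))), "negative")
})

test_that("median subtype split assigns ties to Lo and profiles both arms", {
    expr <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 2, 4, byrow = TRUE,
                   dimnames = list(c("G1", "G2"), paste0("c", 1:4)))
    meta <- data.frame(cell_id = colnames(expr), patient_id = "P1",
                       cell_type = "TC")
    co <- AnnotatedCohort(expr, meta,
                          matrix(1, 1, 1, dimnames = list("P1", "D")))
    sp <- subtypeSplit(co, "G1", "TC")
    expect_identical(unname(sp$labels), c("Lo", "Lo", "Hi", "Hi"))
    expect_equal(sp$profiles["G1", "Hi"], 3.5)
    expect_equal(sp$profiles["G1", "Lo"], 1.5)
    # ties at the median go Lo; split sizes differ by at most the tie count
    expr2 <- matrix(c(1, 2, 2, 4, 9, 9, 9, 9), 2, 4, byrow = TRUE,
                    dimnames = list(c("G1", "G2"), paste0("c", 1:4)))
    co2 <- AnnotatedCohort(expr2, meta,
                           matrix(1, 1, 1, dimnames = list("P1", "D")))
    sp2 <- subtypeSplit(co2, "G1", "TC")
    expect_identical(unname(sp2$labels), c("Lo", "Lo", "Lo", "Hi"))
    nt <- sum(expr2["G1", ] == stats::median(expr2["G1", ]))
    expect_lte(abs(sum(sp2$labels == "Hi") - sum(sp2$labels == "Lo")), nt)
    expect_error(subtypeSplit(co2, "G2", "TC"), "degenerate")
})

test_that("combinatorial stratification partitions the cohort", {
    expr <- matrix(1, 2, 6, dimnames = list(c("G1", "G2"),
                                            paste0("b", 1:6)))
    clin <- data.frame(sample = paste0("b", 1:6),
                       time = c(5, 8, 3, 9, 4, 7),
                       event = c(1, 0, 1, 1, 0, 1))
    bulk <- BulkCohort(expr, clin)
    ab <- cbind(G1 = c(.1, .2, .3, .4, .5, .6),
                G2 = c(.6, .5, .4, .3, .2, .1))
    rownames(ab) <- paste0("b", 1:6)
    st <- stratifyBulk(bulk, ab)
    expect_identical(sort(unique(st$group)),
                     c("G1Hi/G2Lo", "G1Lo/G2Hi"))
    expect_identical(nrow(st), 6L)
    expect_identical(sum(table(st$group)), 6L)
    # one gene, four patients: clean median halves
    clin4 <- clin[1:4, ]
    st1 <- stratifyBulk(BulkCohort(expr[, 1:4], clin4),
                        ab[1:4, 1, drop = FALSE])
    expect_identical(st1$group, c("G1Lo", "G1Lo", "G1Hi", "G1Hi"))
    badAb <- ab
    rownames(badAb) <- paste0("x", 1:6)
    expect_error(stratifyBulk(bulk, badAb), "cover")
})

test_that("multi-group log-rank matches hand computation and symmetry", {
    # two identical survival groups: statistic ~ 0, p ~ 1
    clin <- data.frame(sample = paste0("s", 1:8),
                       time = rep(c(2, 4, 6, 8), 2),
                       event = rep(c(1, 1, 0, 1), 2))
    strat <- data.frame(sample = paste0("s", 1:8),
                        group = rep(c("A", "B"), each = 4))
    strat$sample <- paste0("s", c(1:4, 1:4 + 4))
    res <- logrankGroups(strat, clin)
    expect_lt(res$chisq, 1e-10)
    expect_gt(res$p, 0.999)
    # toy table checked against by-hand expectation/variance sums:
    # A events at t=1,2; B censored at t=3,4
    clin2 <- data.frame(sample = paste0("s", 1:4),
                        time = c(1, 2, 3, 4), event = c(1, 1, 0, 0))
    strat2 <- data.frame(sample = paste0("s", 1:4),
                         group = c("A", "A", "B", "B"))
    res2 <- logrankGroups(strat2, clin2)
    # t=1: n=4 (2A), O_A=1, E_A=1/2, V=1/4; t=2: n=3 (1A), O_A=1,
    # E_A=1/3, V=2/9 -> U=7/6, V=17/36, chisq=U^2/V=49/17
    expect_equal(res2$chisq, 49 / 17, tolerance = 1e-8)
    expect_identical(res2$df, 1L)
    expect_equal(res2$p, pchisq(49 / 17, 1, lower.tail = FALSE))
    expect_error(logrankGroups(
        data.frame(sample = paste0("s", 1:4), group = "A"), clin2),
        "fewer than two")
    km <- kmCurves(strat2, clin2)
    expect_true(all(c("group", "time", "surv") %in% colnames(km)))
    expect_true(all(km$surv >= 0 & km$surv <= 1))
})

test_that("NNLS deconvolution recovers exact and noisy mixtures", {
    withr::with_seed(4, {
        S <- matrix(rexp(40, 0.2), 20, 2,
                    dimnames = list(paste0("g", 1:20), c("Hi", "Lo")))
        w <- c(0.5, 0.5)
        y <- S %*% w
        colnames(y) <- "s1"
        est <- nnlsDeconvolve(y, S)
        expect_equal(unname(est["s1", ]), w, tolerance = 1e-8)
        # pure column
        y2 <- S[, 1, drop = FALSE]
        colnames(y2) <- "s2"
        expect_equal(unname(nnlsDeconvolve(y2, S)["s2", ]), c(1, 0),
                     tolerance = 1e-8)
        # noise degrades recovery gracefully
        w3 <- c(0.3, 0.7)
        y3 <- S %*% w3 + matrix(rnorm(20, sd = 0.05), 20)
        colnames(y3) <- "s3"
        expect_equal(unname(nnlsDeconvolve(y3, S)["s3", ]), w3,
                     tolerance = 0.05)
    })
    expect_error(nnlsDeconvolve(y3 <- matrix(1, 2, 1,
        dimnames = list(c("g1", "g2"), "s")), matrix(1, 2, 2,
        dimnames = list(c("g1", "g2"), c("a", "b")))), "rank")
})
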