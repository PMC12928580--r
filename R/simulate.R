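#' Planted communication motifs for synthetic cohorts
#'
#' Three driver-associated motifs (present with probability
#' \code{pPlus} = 0.9 in driver-positive samples and \code{pMinus} = 0.1
#' otherwise; one of them a two-edge ligand-receptor-target path) and three
#' null motifs whose presence is independent of the driver. A motif is a
#' small labeled subgraph plus its two conditional presence probabilities;
#' the planted effect is the log odds ratio they imply.
#'
#' @param pPlus,pMinus conditional presence probabilities of the
#'   associated motifs given driver status.
#' @param pNull presence probability of the null motifs (both arms).
#' @return list of motif definitions (name, edges, pPlus, pMinus).
#' @export
defaultMotifs <- function(pPlus = 0.9, pMinus = 0.1, pNull = 0.3) {
    edge <- function(ga, ta, gb, tb)
        data.frame(gene_a = ga, type_a = ta, gene_b = gb, type_b = tb,
                   stringsAsFactors = FALSE)
    list(
        list(name = "assoc1", pPlus = pPlus, pMinus = pMinus,
             edges = edge("LIG1", "TC", "REC1", "Mph")),
        list(name = "assoc2", pPlus = pPlus, pMinus = pMinus,
             edges = edge("LIG2", "Mph", "REC2", "CTL")),
        list(name = "assoc3", pPlus = pPlus, pMinus = pMinus,
             edges = rbind(edge("LIG3", "TC", "REC3", "Mph"),
                           edge("REC3", "Mph", "TGT3", "Mph"))),
        list(name = "null1", pPlus = pNull, pMinus = pNull,
             edges = edge("LIG4", "TC", "REC4", "CTL")),
        list(name = "null2", pPlus = pNull, pMinus = pNull,
             edges = edge("LIG5", "CTL", "REC5", "Mph")),
        list(name = "null3", pPlus = pNull, pMinus = pNull,
             edges = edge("LIG6", "Mph", "REC6", "TC")))
}

#' Configuration of the synthetic-cohort generators
#'
#' Bundles and validates the study conditions emulated by
#' [simulateNetworkCohort()] and [simulateExpressionCohort()]: cohort
#' sizes, driver prevalence, planted motifs with their conditional
#' presence probabilities, background network density, and the
#' negative-binomial expression model.
#'
#' @param nSamples number of (pseudo-)samples for the network-level
#'   generator (default 60).
#' @param driverPrevalence Bernoulli probability of driver-positive status
#'   (default 0.4).
#' @param motifs motif list as produced by [defaultMotifs()].
#' @param backgroundGenes gene symbols usable for background edges; must
#'   not collide with motif genes.
#' @param cellTypes cell-type vocabulary (>= 3 types).
#' @param backgroundEdgesPerSample random background edges added per
#'   sample network (default 5).
#' @param nPatients patients for the expression-level generator
#'   (default 12).
#' @param cellsPerType cells per patient per cell type (default 60).
#' @param nbMu,nbSize baseline negative-binomial mean and dispersion size
#'   per (gene, cell) count (defaults 0.3 and 1).
#' @param plantedMu elevated mean of a motif gene in the designated cell
#'   type of motif-carrying patients (default 3).
#' @param seed master seed; all draws derive from it.
#' @return validated configuration list (class \code{sim_config}).
#' @export
simConfig <- function(nSamples = 60L, driverPrevalence = 0.4,
                      motifs = defaultMotifs(),
                      backgroundGenes = sprintf("BG%02d", 1:30),
                      cellTypes = c("TC", "Mph", "CTL"),
                      backgroundEdgesPerSample = 5L,
                      nPatients = 12L, cellsPerType = 60L,
                      nbMu = 0.3, nbSize = 1, plantedMu = 3,
                      seed = 1L) {
    stopifnot(driverPrevalence > 0, driverPrevalence < 1,
              nSamples >= 2L, length(cellTypes) >= 2L)
    for (m in motifs) {
        if (m$pPlus < 0 || m$pPlus > 1 || m$pMinus < 0 || m$pMinus > 1)
            stop("motif presence probabilities must lie in [0, 1]")
        bad <- setdiff(unique(c(m$edges$type_a, m$edges$type_b)), cellTypes)
        if (length(bad))
            stop("motif ", m$name, " uses undeclared cell type(s): ",
                 paste(bad, collapse = ", "))
    }
    motifGenes <- unique(unlist(lapply(motifs, function(m)
        c(m$edges$gene_a, m$edges$gene_b))))
    clash <- intersect(motifGenes, backgroundGenes)
    if (length(clash))
        stop("motif gene labels collide with the background label space: ",
             paste(clash, collapse = ", "))
    structure(list(nSamples = as.integer(nSamples),
                   driverPrevalence = driverPrevalence, motifs = motifs,
                   backgroundGenes = backgroundGenes,
                   cellTypes = cellTypes,
                   backgroundEdgesPerSample =
                       as.integer(backgroundEdgesPerSample),
                   nPatients = as.integer(nPatients),
                   cellsPerType = as.integer(cellsPerType),
                   nbMu = nbMu, nbSize = nbSize, plantedMu = plantedMu,
                   seed = as.integer(seed)),
              class = "sim_config")
}

motifAssociated <- function(m) m$pPlus != m$pMinus

#' Simulate per-sample communication networks with planted motifs
#'
#' Each sample's driver status is Bernoulli(driverPrevalence); each motif
#' is inserted with its conditional probability given that status; random
#' background edges are drawn over the background (gene, cell type) label
#' space. This is the direct test path for mining and association - no
#' expression model or network backend in between.
#'
#' @param cfg a [simConfig()] configuration.
#' @return list with \code{networks} (list of
#'   \linkS4class{MCTCNetwork}), \code{drivers} (samples x 1 0/1 matrix),
#'   \code{truth} (motif name, p_plus, p_minus, associated) and
#'   \code{presence} (samples x motifs 0/1 matrix).
#' @export
simulateNetworkCohort <- function(cfg) {
    stopifnot(inherits(cfg, "sim_config"))
    withSeed(cfg$seed, {
        ids <- sprintf("S%03d", seq_len(cfg$nSamples))
        drivers <- matrix(stats::rbinom(cfg$nSamples, 1L,
                                        cfg$driverPrevalence),
                          ncol = 1L, dimnames = list(ids, "DRV"))
        presence <- matrix(0L, cfg$nSamples, length(cfg$motifs),
                           dimnames = list(ids, vapply(cfg$motifs,
                               function(m) m$name, "")))
        labelGrid <- expand.grid(gene = cfg$backgroundGenes,
                                 cell_type = cfg$cellTypes,
                                 stringsAsFactors = FALSE)
        networks <- vector("list", cfg$nSamples)
        for (i in seq_len(cfg$nSamples)) {
            edges <- emptyEdges()
            for (k in seq_along(cfg$motifs)) {
                m <- cfg$motifs[[k]]
                pr <- if (drivers[i, 1L] == 1L) m$pPlus else m$pMinus
                if (stats::rbinom(1L, 1L, pr) == 1L) {
                    presence[i, k] <- 1L
                    edges <- rbind(edges, cbind(m$edges,
                        kind = edgeKindFor(m$edges$type_a,
                                           m$edges$type_b)))
                }
            }
            nbg <- cfg$backgroundEdgesPerSample
            if (nbg > 0L) {
                ia <- sample.int(nrow(labelGrid), nbg, replace = TRUE)
                ib <- sample.int(nrow(labelGrid), nbg, replace = TRUE)
                ok <- ia != ib
                if (any(ok))
                    edges <- rbind(edges, data.frame(
                        gene_a = labelGrid$gene[ia[ok]],
                        type_a = labelGrid$cell_type[ia[ok]],
                        gene_b = labelGrid$gene[ib[ok]],
                        type_b = labelGrid$cell_type[ib[ok]],
                        kind = edgeKindFor(labelGrid$cell_type[ia[ok]],
                                           labelGrid$cell_type[ib[ok]]),
                        stringsAsFactors = FALSE))
            }
            networks[[i]] <- MCTCNetwork(ids[i], edges)
        }
        truth <- data.frame(
            motif = colnames(presence),
            p_plus = vapply(cfg$motifs, function(m) m$pPlus, 0),
            p_minus = vapply(cfg$motifs, function(m) m$pMinus, 0),
            associated = vapply(cfg$motifs, motifAssociated, TRUE),
            stringsAsFactors = FALSE)
        list(networks = networks, drivers = drivers, truth = truth,
             presence = presence)
    })
}

#' Match planted motifs to mined patterns
#'
#' A mined pattern matches a motif when their undirected labeled edge sets
#' are identical.
#'
#' @param motifs motif list (see [defaultMotifs()]).
#' @param patterns list of \linkS4class{FrequentSubnetwork}.
#' @return named integer vector of pattern ids (NA when a motif was not
#'   mined).
#' @export
matchMotifs <- function(motifs, patterns) {
    keyOf <- function(ed) paste(sort(edgeKey(ed)), collapse = " ")
    patKeys <- vapply(patterns, function(p) keyOf(netEdges(p)), "")
    out <- vapply(motifs, function(m) {
        hit <- which(patKeys == keyOf(m$edges))
        if (length(hit)) patterns[[hit[1L]]]@patternId else NA_integer_
    }, 0L)
    names(out) <- vapply(motifs, function(m) m$name, "")
    out
}

#' Simulate a full expression-level cohort with planted motifs
#'
#' The integration test path: per-patient driver status and motif carriage
#' are drawn as in [simulateNetworkCohort()]; raw counts come from a
#' negative binomial with a baseline mean, and the ligand/receptor genes
#' of carried motifs are shifted to \code{plantedMu} in their designated
#' cell types so that an expression-threshold network backend recovers the
#' planted edges. Counts are log-normalized into the returned cohort;
#' motif carriage and driver truth are stored in the cohort metadata under
#' \code{sim_truth}.
#'
#' @param cfg a [simConfig()] configuration.
#' @return An \linkS4class{AnnotatedCohort}.
#' @export
simulateExpressionCohort <- function(cfg) {
    stopifnot(inherits(cfg, "sim_config"))
    withSeed(cfg$seed, {
        pats <- sprintf("P%02d", seq_len(cfg$nPatients))
        types <- cfg$cellTypes
        motifGenes <- unique(unlist(lapply(cfg$motifs, function(m)
            c(m$edges$gene_a, m$edges$gene_b))))
        genes <- c(motifGenes, cfg$backgroundGenes)
        driver <- stats::rbinom(cfg$nPatients, 1L, cfg$driverPrevalence)
        carriage <- matrix(0L, cfg$nPatients, length(cfg$motifs),
                           dimnames = list(pats, vapply(cfg$motifs,
                               function(m) m$name, "")))
        meta <- list(); cols <- list()
        for (i in seq_len(cfg$nPatients)) {
            for (k in seq_along(cfg$motifs)) {
                m <- cfg$motifs[[k]]
                pr <- if (driver[i] == 1L) m$pPlus else m$pMinus
                carriage[i, k] <- stats::rbinom(1L, 1L, pr)
            }
            # per-(gene, type) mean for this patient
            mu <- matrix(cfg$nbMu, length(genes), length(types),
                         dimnames = list(genes, types))
            for (k in seq_along(cfg$motifs)) {
                if (carriage[i, k] == 0L) next
                ed <- cfg$motifs[[k]]$edges
                for (r in seq_len(nrow(ed))) {
                    mu[ed$gene_a[r], ed$type_a[r]] <- cfg$plantedMu
                    mu[ed$gene_b[r], ed$type_b[r]] <- cfg$plantedMu
                }
            }
            for (t in types) {
                n <- cfg$cellsPerType
                counts <- matrix(stats::rnbinom(length(genes) * n,
                                                mu = mu[, t],
                                                size = cfg$nbSize),
                                 length(genes), n)
                rownames(counts) <- genes
                colnames(counts) <- sprintf("%s_%s_%03d", pats[i], t,
                                            seq_len(n))
                cols[[length(cols) + 1L]] <- counts
                meta[[length(meta) + 1L]] <- data.frame(
                    cell_id = colnames(counts), patient_id = pats[i],
                    cell_type = t, stringsAsFactors = FALSE)
            }
        }
        countsAll <- do.call(cbind, cols)
        metaAll <- do.call(rbind, meta)
        metaAll$cell_type <- factor(metaAll$cell_type, levels = types)
        drv <- matrix(driver, ncol = 1L, dimnames = list(pats, "DRV"))
        cohort <- AnnotatedCohort(countsAll, metaAll, drv,
                                  normalize = TRUE)
        metadata(cohort)$sim_truth <- list(
            carriage = carriage,
            truth = data.frame(
                motif = colnames(carriage),
                p_plus = vapply(cfg$motifs, function(m) m$pPlus, 0),
                p_minus = vapply(cfg$motifs, function(m) m$pMinus, 0),
                associated = vapply(cfg$motifs, motifAssociated, TRUE),
                stringsAsFactors = FALSE))
        cohort
    })
}

#' Write a simulated cohort plus its truth table to disk
#'
#' @param cohort cohort from [simulateExpressionCohort()].
#' @param dir output directory.
#' @return Invisibly, the written file paths.
#' @export
writeSimulatedCohort <- function(cohort, dir) {
    paths <- writeCohort(cohort, dir)
    st <- metadata(cohort)$sim_truth
    if (!is.null(st)) {
        tp <- file.path(dir, "truth.tsv")
        utils::write.table(st$truth, tp, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        cp <- file.path(dir, "carriage.tsv")
        utils::write.table(data.frame(patient = rownames(st$carriage),
                                      st$carriage, check.names = FALSE),
                           cp, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths <- c(paths, tp, cp)
    }
    invisible(paths)
}
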