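#' Construct an annotated cohort from in-memory pieces
#'
#' @param expr gene x cell numeric matrix. Interpreted as log-normalized
#'   expression unless \code{normalize = TRUE}, in which case it is taken as
#'   raw counts and passed through [logNormalizeCounts()].
#' @param cellMeta data.frame with columns \code{cell_id}, \code{patient_id},
#'   \code{cell_type}, one row per column of \code{expr} (same order or
#'   matched by \code{cell_id}).
#' @param driverAnnot patient x driver 0/1 matrix with patient rownames.
#' @param normalize logical; normalize raw counts (default \code{FALSE},
#'   i.e. the input is already log-normalized).
#' @param scale library-size scale factor used when normalizing.
#'
#' @return A validated \linkS4class{AnnotatedCohort}.
#' @examples
#' expr <- matrix(rpois(12, 2), 3, 4,
#'                dimnames = list(paste0("G", 1:3), paste0("c", 1:4)))
#' meta <- data.frame(cell_id = paste0("c", 1:4),
#'                    patient_id = rep(c("P1", "P2"), each = 2),
#'                    cell_type = c("TC", "Mph", "TC", "Mph"))
#' drv <- matrix(c(1, 0), 2, 1, dimnames = list(c("P1", "P2"), "KRAS"))
#' AnnotatedCohort(expr, meta, drv, normalize = TRUE)
#' @export
AnnotatedCohort <- function(expr, cellMeta, driverAnnot, normalize = FALSE,
                            scale = 1e4) {
    expr <- as.matrix(expr)
    if (is.null(rownames(expr)) || is.null(colnames(expr)))
        stop("expression matrix needs gene rownames and cell colnames")
    need <- c("cell_id", "patient_id", "cell_type")
    if (!all(need %in% colnames(cellMeta)))
        stop("cellMeta needs columns ", paste(need, collapse = ", "))
    if (nrow(cellMeta) != ncol(expr))
        stop("cellMeta rows (", nrow(cellMeta),
             ") do not match expression columns (", ncol(expr), ")")
    cellMeta <- cellMeta[match(colnames(expr), cellMeta$cell_id), ]
    if (anyNA(cellMeta$cell_id))
        stop("cellMeta cell_id does not cover all expression columns")
    driverAnnot <- as.matrix(driverAnnot)
    miss <- setdiff(unique(as.character(cellMeta$patient_id)),
                    rownames(driverAnnot))
    if (length(miss))
        stop("patients missing from driver annotation: ",
             paste(miss, collapse = ", "))
    assays <- if (normalize) {
        list(counts = expr, logcounts = logNormalizeCounts(expr, scale))
    } else list(logcounts = expr)
    ct <- cellMeta$cell_type
    if (!is.factor(ct)) ct <- factor(ct)
    sce <- SingleCellExperiment(
        assays = assays,
        colData = DataFrame(patient_id = as.character(cellMeta$patient_id),
                            cell_type = ct,
                            row.names = colnames(expr)))
    new("AnnotatedCohort", sce, driverAnnot = driverAnnot)
}

#' Library-size log-normalization of raw counts
#'
#' Per cell, each count is scaled to \code{scale} total counts and
#' log-transformed: \code{log(1 + count / colsum * scale)} (natural log).
#' All-zero cells are left all-zero with a warning.
#'
#' @param counts gene x cell non-negative count matrix.
#' @param scale target library size (default 10,000).
#' @return Matrix of the same shape with log-normalized values.
#' @examples
#' logNormalizeCounts(matrix(c(3, 7), 2, 1,
#'                    dimnames = list(c("a", "b"), "c1")), scale = 10)
#' @export
logNormalizeCounts <- function(counts, scale = 1e4) {
    counts <- as.matrix(counts)
    if (min(counts) < 0) stop("negative counts are not allowed")
    cs <- colSums(counts)
    if (any(cs == 0)) {
        warning(sum(cs == 0), " all-zero cell(s) left unnormalized")
        cs[cs == 0] <- 1
    }
    log1p(sweep(counts, 2L, cs, "/") * scale)
}

#' Read an annotated cohort from disk
#'
#' Expression is either a dense TSV (genes in rows, header row of cell ids)
#' or a MatrixMarket \code{.mtx} file with gene/cell sidecar files (one
#' identifier per line). Per-cell metadata and driver annotations are TSVs;
#' when a protein-coding gene list is given, genes are restricted to it
#' (case-sensitive symbols, surrounding whitespace stripped).
#'
#' @param exprPath expression file (\code{.tsv} dense or \code{.mtx}).
#' @param cellMetaPath TSV with columns cell_id, patient_id, cell_type.
#' @param driverPath TSV, first column patient id, remaining columns 0/1
#'   driver indicators.
#' @param proteinCodingPath optional text file of protein-coding symbols.
#' @param genesPath,cellsPath sidecar files for \code{.mtx} input; default
#'   \code{genes.tsv} / \code{cells.tsv} next to the matrix.
#' @param cellTypeVocabulary optional character vector declaring the allowed
#'   cell types; metadata outside it is a validation error. Defaults to the
#'   types observed in the metadata.
#' @inheritParams AnnotatedCohort
#' @return An \linkS4class{AnnotatedCohort}.
#' @seealso [writeCohort()] for the inverse operation.
#' @export
readCohort <- function(exprPath, cellMetaPath, driverPath,
                       proteinCodingPath = NULL, genesPath = NULL,
                       cellsPath = NULL, cellTypeVocabulary = NULL,
                       normalize = FALSE, scale = 1e4) {
    if (grepl("\\.mtx$", exprPath)) {
        if (is.null(genesPath))
            genesPath <- file.path(dirname(exprPath), "genes.tsv")
        if (is.null(cellsPath))
            cellsPath <- file.path(dirname(exprPath), "cells.tsv")
        m <- as.matrix(Matrix::readMM(exprPath))
        genes <- trimws(readLines(genesPath))
        cells <- trimws(readLines(cellsPath))
        if (length(genes) != nrow(m))
            stop("gene sidecar length does not match matrix rows: ",
                 genesPath)
        if (length(cells) != ncol(m))
            stop("cell sidecar length does not match matrix columns: ",
                 cellsPath)
        dimnames(m) <- list(genes, cells)
    } else {
        df <- readTsv(exprPath, row.names = 1L)
        m <- as.matrix(df)
        rownames(m) <- trimws(rownames(m))
    }
    meta <- readTsv(cellMetaPath)
    if (nrow(meta) != ncol(m))
        stop("cell metadata rows do not match expression columns: ",
             cellMetaPath)
    drvDf <- readTsv(driverPath, row.names = 1L)
    drv <- as.matrix(drvDf)
    if (!is.null(proteinCodingPath)) {
        coding <- trimws(readLines(proteinCodingPath))
        keep <- rownames(m) %in% coding
        if (!any(keep))
            stop("no genes left after protein-coding restriction: ",
                 proteinCodingPath)
        m <- m[keep, , drop = FALSE]
    }
    if (!is.null(cellTypeVocabulary)) {
        unknown <- setdiff(unique(meta$cell_type), cellTypeVocabulary)
        if (length(unknown))
            stop("unknown cell type(s) in ", cellMetaPath, ": ",
                 paste(unknown, collapse = ", "))
        meta$cell_type <- factor(meta$cell_type,
                                 levels = cellTypeVocabulary)
    }
    AnnotatedCohort(m, meta, drv, normalize = normalize, scale = scale)
}

#' Write a cohort to a directory in the plain-text input formats
#'
#' @param cohort an \linkS4class{AnnotatedCohort}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written (expr.tsv, cell_meta.tsv,
#'   drivers.tsv).
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    exprPath <- file.path(dir, "expr.tsv")
    m <- exprMatrix(cohort)
    utils::write.table(data.frame(gene = rownames(m), m,
                                  check.names = FALSE),
                       exprPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    metaPath <- file.path(dir, "cell_meta.tsv")
    utils::write.table(cellMeta(cohort), metaPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    drvPath <- file.path(dir, "drivers.tsv")
    da <- driverAnnot(cohort)
    utils::write.table(data.frame(patient = rownames(da), da,
                                  check.names = FALSE),
                       drvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(exprPath, metaPath, drvPath))
}

#' Mark low-expressed genes per cell type
#'
#' A gene is retained for a given cell type when the fraction of that type's
#' cells with expression above zero is at least \code{minFrac}. Retention is
#' recorded as a per-(gene, cell type) logical mask (accessible with
#' [retentionMask()]); no genes are dropped globally, so different cell
#' types may keep different gene sets downstream. Applying the filter twice
#' is a no-op.
#'
#' @param cohort an \linkS4class{AnnotatedCohort}.
#' @param minFrac minimum expressing-cell fraction (default 0.05).
#' @return The cohort with the retention mask recorded in its metadata.
#' @export
filterLowExpressed <- function(cohort, minFrac = 0.05) {
    stopifnot(is(cohort, "AnnotatedCohort"),
              minFrac >= 0, minFrac <= 1)
    types <- cohortCellTypes(cohort)
    ct <- colData(cohort)$cell_type
    counts <- table(ct)
    empty <- types[counts[types] == 0L | is.na(counts[types])]
    if (length(empty))
        stop("cell type(s) with zero cells: ", paste(empty, collapse = ", "))
    m <- exprMatrix(cohort)
    mask <- vapply(types, function(t) {
        rowMeans(m[, ct == t, drop = FALSE] > 0) >= minFrac
    }, logical(nrow(m)))
    mask <- matrix(mask, nrow = nrow(m), ncol = length(types),
                   dimnames = list(rownames(m), types))
    metadata(cohort)$retention <- mask
    metadata(cohort)$retention_min_frac <- minFrac
    cohort
}

#' Read a ligand-receptor pair table
#'
#' @param path two-column TSV (ligand, receptor), header optional but the
#'   first line is treated as a header when it matches
#'   \code{ligand<TAB>receptor}.
#' @return data.frame with columns \code{ligand}, \code{receptor},
#'   duplicates removed, symbols whitespace-stripped.
#' @export
readLigandReceptorTable <- function(path) {
    first <- readLines(path, n = 1L)
    header <- identical(tolower(strsplit(first, "\t")[[1]][1:2]),
                        c("ligand", "receptor"))
    df <- readTsv(path, header = header)
    if (ncol(df) < 2L) stop("ligand-receptor table needs two columns: ", path)
    out <- data.frame(ligand = trimws(df[[1]]), receptor = trimws(df[[2]]),
                      stringsAsFactors = FALSE)
    if (any(!nzchar(out$ligand)) || any(!nzchar(out$receptor)))
        stop("empty gene symbols in ligand-receptor table: ", path)
    out[!duplicated(paste(out$ligand, out$receptor)), , drop = FALSE]
}

#' Read an undirected intracellular gene-interaction network
#'
#' @param path two-column TSV edge list of gene symbols.
#' @return data.frame with columns \code{gene_a}, \code{gene_b}; self-loops
#'   rejected, unordered duplicates removed.
#' @export
readIntracellularNetwork <- function(path) {
    df <- readTsv(path, header = FALSE)
    if (ncol(df) < 2L) stop("intracellular network needs two columns: ", path)
    out <- data.frame(gene_a = trimws(df[[1]]), gene_b = trimws(df[[2]]),
                      stringsAsFactors = FALSE)
    if (any(out$gene_a == out$gene_b))
        stop("self-loops are not allowed in the intracellular network: ",
             path)
    key <- paste(pmin(out$gene_a, out$gene_b),
                 pmax(out$gene_a, out$gene_b))
    out[!duplicated(key), , drop = FALSE]
}

#' Construct / read a bulk cohort with clinical follow-up
#'
#' @param expr gene x sample matrix, or for \code{readBulkCohort} a dense
#'   TSV path (genes in rows).
#' @param clinical data.frame (or TSV path) with columns sample, time,
#'   event.
#' @return A \linkS4class{BulkCohort}.
#' @export
BulkCohort <- function(expr, clinical) {
    new("BulkCohort", expr = as.matrix(expr),
        clinical = as.data.frame(clinical))
}

#' @rdname BulkCohort
#' @param exprPath,clinicalPath file paths for the TSV reader.
#' @export
readBulkCohort <- function(exprPath, clinicalPath) {
    expr <- as.matrix(readTsv(exprPath, row.names = 1L))
    clinical <- readTsv(clinicalPath)
    BulkCohort(expr, clinical)
}
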