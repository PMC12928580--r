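#' Read one patient's inferred CNV profile pair
#'
#' Consumes externally inferred copy-number matrices (genes x cells) for
#' the tumor compartment and for reference diploid cells, as dense TSVs
#' with gene rownames and cell id header.
#'
#' @param tumorPath,refPath TSV paths.
#' @return list with matrices \code{tumor} and \code{reference}, restricted
#'   to their shared genes.
#' @export
readCNVProfile <- function(tumorPath, refPath) {
    tumor <- as.matrix(readTsv(tumorPath, row.names = 1L))
    reference <- as.matrix(readTsv(refPath, row.names = 1L))
    genes <- intersect(rownames(tumor), rownames(reference))
    if (!length(genes))
        stop("tumor and reference CNV matrices share no genes")
    list(tumor = tumor[genes, , drop = FALSE],
         reference = reference[genes, , drop = FALSE])
}

#' Call per-patient driver genes from CNV profiles
#'
#' For each patient and each candidate driver gene, the distribution of the
#' gene's inferred CNV values across tumor cells is compared to its
#' distribution across reference diploid cells with a two-sided two-sample
#' Kolmogorov-Smirnov test. P-values are Benjamini-Hochberg adjusted
#' (within each patient by default) and a gene is called a driver when its
#' adjusted p falls below \code{alpha}. Candidate genes missing from a
#' patient's matrices are skipped with a warning.
#'
#' @param profiles named list (one entry per patient) of lists with
#'   matrices \code{tumor} and \code{reference} (genes x cells, >= 2 cells
#'   each).
#' @param candidates character vector of candidate driver gene symbols.
#' @param alpha adjusted-p threshold (default 0.01).
#' @param family \code{"per_patient"} (default) BH within each patient, or
#'   \code{"global"} across all patient-gene tests.
#' @return list with \code{calls} (patients x candidates 0/1 matrix, the
#'   driver annotation consumed by [AnnotatedCohort()]) and \code{stats}
#'   (long data.frame: patient, gene, D, p, p_adj, called).
#' @export
ksDriverCall <- function(profiles, candidates, alpha = 0.01,
                         family = c("per_patient", "global")) {
    family <- match.arg(family)
    if (is.null(names(profiles))) stop("profiles must be named by patient")
    rows <- list()
    for (pt in names(profiles)) {
        pr <- profiles[[pt]]
        if (ncol(pr$tumor) < 2L || ncol(pr$reference) < 2L)
            stop("patient ", pt, " needs >= 2 cells per compartment")
        genes <- intersect(rownames(pr$tumor), rownames(pr$reference))
        miss <- setdiff(candidates, genes)
        if (length(miss))
            warning("patient ", pt, ": candidate gene(s) missing from the ",
                    "CNV matrices, skipped: ", paste(miss, collapse = ", "))
        for (g in intersect(candidates, genes)) {
            kt <- suppressWarnings(
                stats::ks.test(pr$tumor[g, ], pr$reference[g, ]))
            rows[[length(rows) + 1L]] <- data.frame(
                patient = pt, gene = g, D = unname(kt$statistic),
                p = kt$p.value, stringsAsFactors = FALSE)
        }
    }
    stats_ <- do.call(rbind, rows)
    if (is.null(stats_))
        stop("no candidate gene could be tested in any patient")
    if (family == "per_patient") {
        stats_$p_adj <- stats::ave(stats_$p, stats_$patient,
                                   FUN = function(p)
                                       stats::p.adjust(p, "BH"))
    } else {
        stats_$p_adj <- stats::p.adjust(stats_$p, "BH")
    }
    stats_$called <- stats_$p_adj < alpha
    calls <- matrix(0L, length(names(profiles)), length(candidates),
                    dimnames = list(names(profiles), candidates))
    hit <- stats_[stats_$called, , drop = FALSE]
    if (nrow(hit)) calls[cbind(hit$patient, hit$gene)] <- 1L
    list(calls = calls, stats = stats_)
}
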