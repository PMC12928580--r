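#' Patients eligible for pseudo-sample resampling
#'
#' A patient is eligible when it has at least \code{minCells} cells in
#' every focal cell type; all other patients are reported as undersized.
#'
#' @param cohort an \linkS4class{AnnotatedCohort}.
#' @param focalTypes character vector of focal cell types (must belong to
#'   the cohort vocabulary).
#' @param minCells minimum cells per focal type (default 20).
#' @return list with character vectors \code{eligible} and
#'   \code{undersized}.
#' @export
eligiblePatients <- function(cohort, focalTypes, minCells = 20L) {
    stopifnot(is(cohort, "AnnotatedCohort"))
    unknown <- setdiff(focalTypes, cohortCellTypes(cohort))
    if (length(unknown))
        stop("focal type(s) not in the cohort vocabulary: ",
             paste(unknown, collapse = ", "))
    cd <- colData(cohort)
    pats <- patientIds(cohort)
    counts <- table(factor(cd$patient_id, levels = pats),
                    factor(cd$cell_type, levels = cohortCellTypes(cohort)))
    ok <- apply(counts[, focalTypes, drop = FALSE] >= minCells, 1L, all)
    list(eligible = pats[ok], undersized = pats[!ok])
}

#' Bootstrap pseudo-samples from a patient cohort
#'
#' Each eligible patient yields \code{repeats} pseudo-samples; each draws
#' \code{round(frac * n_t)} cells with replacement from the patient's cells
#' of every focal type t (round-half-to-even). When
#' \code{includeUndersized} is on, every undersized patient contributes one
#' pseudo-sample holding all of its cells, with replicate index 0.
#'
#' Randomness is reproducible and insertion-stable: a per-(patient,
#' replicate) stream is derived from \code{seed} by hashing the patient
#' identifier, so adding or removing patients never perturbs another
#' patient's draws.
#'
#' @inheritParams eligiblePatients
#' @param frac fraction of cells drawn per focal type (default 0.5).
#' @param repeats pseudo-samples per eligible patient (default 5).
#' @param includeUndersized include undersized patients directly
#'   (default \code{FALSE}).
#' @param seed integer master seed.
#' @return list of \linkS4class{PseudoSample}; length
#'   \code{length(eligible) * repeats} plus the included undersized
#'   patients.
#' @seealso [pseudosampleManifest()], [psExpression()]
#' @export
generatePseudosamples <- function(cohort, focalTypes, minCells = 20L,
                                  frac = 0.5, repeats = 5L,
                                  includeUndersized = FALSE, seed = 1L) {
    if (repeats < 1L) stop("repeats must be >= 1")
    if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
    el <- eligiblePatients(cohort, focalTypes, minCells)
    cd <- colData(cohort)
    cellsOf <- function(patient, type)
        colnames(cohort)[cd$patient_id == patient & cd$cell_type == type]
    da <- driverAnnot(cohort)
    out <- list()
    for (p in el$eligible) {
        for (r in seq_len(repeats)) {
            draw <- withSeed(streamSeed(seed, p, r), {
                lapply(stats::setNames(focalTypes, focalTypes),
                       function(t) {
                    cells <- cellsOf(p, t)
                    sample(cells, size = round(frac * length(cells)),
                           replace = TRUE)
                })
            })
            out[[length(out) + 1L]] <- new("PseudoSample",
                sampleId = sprintf("%s_rep%d", p, r),
                sourcePatient = p, replicateIndex = as.integer(r),
                cellsByType = draw, driverVector = da[p, ])
        }
    }
    if (includeUndersized) {
        for (p in el$undersized) {
            all <- lapply(stats::setNames(focalTypes, focalTypes),
                          function(t) cellsOf(p, t))
            out[[length(out) + 1L]] <- new("PseudoSample",
                sampleId = sprintf("%s_rep0", p),
                sourcePatient = p, replicateIndex = 0L,
                cellsByType = all, driverVector = da[p, ])
        }
    }
    out
}

#' Manifest table of a pseudo-sample list
#'
#' @param psList list of \linkS4class{PseudoSample}.
#' @param path optional TSV path to write the manifest to.
#' @return data.frame with sample_id, source_patient, replicate_index and
#'   one cell-count column per focal type.
#' @export
pseudosampleManifest <- function(psList, path = NULL) {
    types <- names(psList[[1]]@cellsByType)
    df <- data.frame(
        sample_id = vapply(psList, sampleId, ""),
        source_patient = vapply(psList, function(p) p@sourcePatient, ""),
        replicate_index = vapply(psList, function(p) p@replicateIndex, 0L),
        stringsAsFactors = FALSE)
    for (t in types)
        df[[paste0("n_", t)]] <-
            vapply(psList, function(p) length(p@cellsByType[[t]]), 0L)
    if (!is.null(path))
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    df
}

#' Expression submatrix of one pseudo-sample and cell type
#'
#' Columns repeat when a cell was drawn more than once, so expressing-cell
#' fractions are computed over the bootstrap multiset.
#'
#' @param cohort the source \linkS4class{AnnotatedCohort}.
#' @param ps a \linkS4class{PseudoSample}.
#' @param type focal cell type.
#' @return gene x selected-cell matrix.
#' @export
psExpression <- function(cohort, ps, type) {
    cells <- ps@cellsByType[[type]]
    if (is.null(cells))
        stop("pseudo-sample has no cells of type ", type)
    exprMatrix(cohort)[, cells, drop = FALSE]
}

#' Driver annotation matrix aligned to a pseudo-sample list
#'
#' @param psList list of \linkS4class{PseudoSample}.
#' @return 0/1 matrix, pseudo-samples x drivers; each row is the source
#'   patient's annotation.
#' @export
psDriverMatrix <- function(psList) {
    m <- do.call(rbind, lapply(psList, function(p) p@driverVector))
    rownames(m) <- vapply(psList, sampleId, "")
    m
}
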