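#' Split one cell type into Hi/Lo subtypes by a gene's median expression
#'
#' Cells of the given type with expression strictly above the median are
#' labeled Hi; cells at or below the median (including ties at the median)
#' are Lo. The mean expression profiles of the two subtypes are returned as
#' columns usable in a deconvolution signature matrix.
#'
#' @param cohort an \linkS4class{AnnotatedCohort}.
#' @param gene gene symbol (must be retained for the cell type when a
#'   retention mask is present).
#' @param cellType cell type to split.
#' @return list with \code{labels} (named Hi/Lo per cell),
#'   \code{profiles} (genes x 2 matrix, columns Hi and Lo), \code{gene},
#'   \code{cellType} and the \code{median} used.
#' @export
subtypeSplit <- function(cohort, gene, cellType) {
    stopifnot(is(cohort, "AnnotatedCohort"))
    if (!gene %in% rownames(cohort))
        stop("gene ", gene, " not in the cohort")
    mask <- retentionMask(cohort)
    if (!is.null(mask) && !mask[gene, cellType])
        stop("gene ", gene, " is not retained for cell type ", cellType)
    m <- exprMatrix(cohort)
    cells <- colnames(cohort)[colData(cohort)$cell_type == cellType]
    if (!length(cells)) stop("no cells of type ", cellType)
    v <- m[gene, cells]
    if (length(unique(v)) == 1L)
        stop("all cells of type ", cellType, " express ", gene,
             " identically; a median split is degenerate - pick another ",
             "gene or cell type")
    med <- stats::median(v)
    labels <- ifelse(v > med, "Hi", "Lo")
    names(labels) <- cells
    profiles <- cbind(
        Hi = rowMeans(m[, cells[labels == "Hi"], drop = FALSE]),
        Lo = rowMeans(m[, cells[labels == "Lo"], drop = FALSE]))
    list(labels = labels, profiles = profiles, gene = gene,
         cellType = cellType, median = med)
}

#' Stratify a bulk cohort by subtype-abundance median splits
#'
#' For each signature gene, patients with Hi-subtype abundance strictly
#' above the cohort median are in that gene's "Hi" state (ties go to Lo).
#' The group label of a patient is the combination of its per-gene states,
#' so k genes give up to 2^k non-empty groups that partition the cohort.
#'
#' @param bulk a \linkS4class{BulkCohort}.
#' @param abundance numeric matrix, samples x signature genes: per-sample
#'   abundance of each gene's Hi subtype (e.g. deconvolution output).
#'   Rownames must cover the bulk cohort's clinical samples.
#' @return data.frame with column \code{sample}, one Hi/Lo column per
#'   signature gene, and \code{group}.
#' @export
stratifyBulk <- function(bulk, abundance) {
    stopifnot(is(bulk, "BulkCohort"))
    abundance <- as.matrix(abundance)
    samples <- bulk@clinical$sample
    if (is.null(rownames(abundance)) ||
        !all(samples %in% rownames(abundance)))
        stop("abundance rows do not cover the bulk cohort samples")
    abundance <- abundance[samples, , drop = FALSE]
    states <- apply(abundance, 2L, function(v)
        ifelse(v > stats::median(v), "Hi", "Lo"))
    states <- matrix(states, nrow = length(samples),
                     dimnames = list(samples, colnames(abundance)))
    out <- data.frame(sample = samples, states, check.names = FALSE,
                      stringsAsFactors = FALSE)
    out$group <- apply(states, 1L, function(r)
        paste(paste0(colnames(abundance), r), collapse = "/"))
    rownames(out) <- NULL
    out
}

#' Multi-group log-rank test over a signature stratification
#'
#' Standard k-group log-rank statistic over the survival curves of the
#' stratified groups. Empty groups are dropped with a warning; at least two
#' must remain.
#'
#' @param strat data.frame from [stratifyBulk()] (columns sample, group).
#' @param clinical data.frame with sample, time, event.
#' @return list with \code{chisq}, \code{df}, \code{p} and the underlying
#'   \code{survival::survdiff} fit.
#' @export
logrankGroups <- function(strat, clinical) {
    df <- merge(strat[, c("sample", "group")], clinical, by = "sample")
    if (!nrow(df)) stop("no overlap between stratification and clinical")
    tab <- table(df$group)
    if (any(tab == 0L)) warning("empty group(s) dropped")
    df$group <- factor(df$group)
    if (nlevels(df$group) < 2L)
        stop("fewer than two non-empty groups; nothing to compare")
    if (!any(df$event == 1))
        stop("no events in the stratified cohort")
    fit <- survival::survdiff(survival::Surv(time, event) ~ group,
                              data = df)
    df_ <- length(fit$n) - 1L
    list(chisq = unname(fit$chisq), df = df_,
         p = stats::pchisq(fit$chisq, df_, lower.tail = FALSE),
         fit = fit)
}

#' Kaplan-Meier curve coordinates per group
#'
#' @inheritParams logrankGroups
#' @param path optional TSV path to export the curves.
#' @return data.frame with group, time, n_risk, n_event, surv.
#' @export
kmCurves <- function(strat, clinical, path = NULL) {
    df <- merge(strat[, c("sample", "group")], clinical, by = "sample")
    fit <- survival::survfit(survival::Surv(time, event) ~ group,
                             data = df)
    groups <- sub("^group=", "", rep(names(fit$strata),
                                     times = fit$strata))
    out <- data.frame(group = groups, time = fit$time,
                      n_risk = fit$n.risk, n_event = fit$n.event,
                      surv = fit$surv, stringsAsFactors = FALSE)
    if (!is.null(path))
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    out
}
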