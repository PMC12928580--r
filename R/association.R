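#' One-sided Fisher's exact test for co-occurrence
#'
#' Tests whether a pattern occurs together with a driver more often than
#' expected under independence. With a = driver+ & pattern+, b = driver+ &
#' pattern-, c = driver- & pattern+, d = driver- & pattern-, the p-value is
#' the hypergeometric upper tail P(X >= a) given the margins (alternative
#' "greater"), and the odds ratio is the sample ad/bc (infinite when
#' bc = 0 and a > 0).
#'
#' @param patternCol,driverCol equal-length binary vectors over the same
#'   sample index.
#' @return list with \code{table} (2x2 integer matrix), \code{oddsRatio}
#'   and \code{p}.
#' @examples
#' fisherOneSided(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 0, 0, 0))$p  # 0.05
#' @export
fisherOneSided <- function(patternCol, driverCol) {
    x <- assertBinary(patternCol, "pattern column")
    y <- assertBinary(driverCol, "driver column")
    if (length(x) != length(y))
        stop("pattern and driver vectors differ in length")
    a <- sum(y == 1L & x == 1L)
    b <- sum(y == 1L & x == 0L)
    c_ <- sum(y == 0L & x == 1L)
    d <- sum(y == 0L & x == 0L)
    or <- if (b * c_ == 0) { if (a > 0) Inf else NaN } else (a * d) / (b * c_)
    p <- stats::phyper(a - 1L, m = a + b, n = c_ + d, k = a + c_,
                       lower.tail = FALSE)
    list(table = matrix(c(a, b, c_, d), 2L, byrow = TRUE,
                        dimnames = list(c("driver+", "driver-"),
                                        c("pattern+", "pattern-"))),
         oddsRatio = or, p = p)
}

#' Test all frequent subnetworks against all drivers
#'
#' For every driver with informative prevalence (present in at least one
#' and fewer than all samples; the rest are skipped with a warning), each
#' pattern column of the occurrence matrix is tested with
#' [fisherOneSided()]. P-values are Benjamini-Hochberg adjusted, by default
#' within each driver's family of patterns (\code{family = "global"} pools
#' all driver-pattern tests). Patterns with adjusted p below \code{alpha}
#' are communication signatures; within each driver they are ranked in
#' descending order of significance, ties broken by higher odds ratio, then
#' larger co-occurrence count, then pattern id.
#'
#' @param F an \linkS4class{OccurrenceMatrix}.
#' @param drivers 0/1 matrix, samples x drivers, rows aligned (by name) to
#'   the occurrence matrix.
#' @param alpha significance threshold on adjusted p (default 0.05).
#' @param family multiple-testing family, \code{"per_driver"} (default) or
#'   \code{"global"}.
#' @param patterns optional pattern list to render the \code{signature}
#'   column.
#' @return data.frame with columns driver, pattern_id, a, b, c, d,
#'   odds_ratio, p, p_adj, significant, rank (NA when not significant) and
#'   optionally signature.
#' @export
associateAll <- function(F, drivers, alpha = 0.05,
                         family = c("per_driver", "global"),
                         patterns = NULL) {
    family <- match.arg(family)
    m <- occurrence(F)
    drivers <- as.matrix(drivers)
    if (is.null(rownames(drivers)))
        stop("driver matrix needs sample rownames")
    if (!setequal(rownames(drivers), rownames(m)))
        stop("sample index mismatch between occurrence matrix and drivers")
    drivers <- drivers[rownames(m), , drop = FALSE]
    if (!ncol(m))
        return(data.frame(driver = character(), pattern_id = integer(),
                          a = integer(), b = integer(), c = integer(),
                          d = integer(), odds_ratio = numeric(),
                          p = numeric(), p_adj = numeric(),
                          significant = logical(), rank = integer()))
    prev <- colSums(drivers)
    skip <- prev == 0L | prev == nrow(drivers)
    if (any(skip))
        warning("driver(s) absent or present in all samples, skipped: ",
                paste(colnames(drivers)[skip], collapse = ", "))
    rows <- list()
    for (drv in colnames(drivers)[!skip]) {
        for (j in seq_len(ncol(m))) {
            ft <- fisherOneSided(m[, j], drivers[, drv])
            tb <- ft$table
            rows[[length(rows) + 1L]] <- data.frame(
                driver = drv, pattern_id = as.integer(colnames(m)[j]),
                a = tb[1, 1], b = tb[1, 2], c = tb[2, 1], d = tb[2, 2],
                odds_ratio = ft$oddsRatio, p = ft$p,
                stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, rows)
    if (is.null(res))
        return(data.frame(driver = character(), pattern_id = integer(),
                          a = integer(), b = integer(), c = integer(),
                          d = integer(), odds_ratio = numeric(),
                          p = numeric(), p_adj = numeric(),
                          significant = logical(), rank = integer()))
    if (family == "per_driver") {
        res$p_adj <- stats::ave(res$p, res$driver,
                                FUN = function(p)
                                    stats::p.adjust(p, "BH"))
    } else {
        res$p_adj <- stats::p.adjust(res$p, "BH")
    }
    res$significant <- res$p_adj < alpha
    res$rank <- NA_integer_
    for (drv in unique(res$driver)) {
        sig <- which(res$driver == drv & res$significant)
        if (!length(sig)) next
        o <- order(res$p_adj[sig], -res$odds_ratio[sig], -res$a[sig],
                   res$pattern_id[sig])
        res$rank[sig[o]] <- seq_along(sig)
    }
    if (!is.null(patterns)) {
        notation <- vapply(patterns, signatureNotation, "")
        ids <- vapply(patterns, function(p) p@patternId, 0L)
        res$signature <- notation[match(res$pattern_id, ids)]
    }
    rownames(res) <- NULL
    res
}

#' Write an association result table
#'
#' @param res data.frame from [associateAll()].
#' @param path output TSV.
#' @return Invisibly, \code{path}.
#' @export
writeAssociation <- function(res, path) {
    utils::write.table(res, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
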