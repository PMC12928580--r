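#' Core MHC-I antigen-presentation gene set
#'
#' The nine-gene core of the class-I antigen processing and presentation
#' machinery: HLA-A/B/C, the TAP transporters, the NLRC5 transactivator,
#' the immunoproteasome subunits PSMB8/9 and B2M.
#'
#' @return character vector of nine gene symbols.
#' @export
mhc1CoreSet <- function() {
    c("HLA-A", "HLA-B", "HLA-C", "TAP1", "TAP2", "NLRC5", "PSMB9",
      "PSMB8", "B2M")
}

#' MHC-I antigen presentation score
#'
#' Per-sample arithmetic mean of the core MHC-I gene set; core genes
#' missing from the matrix are dropped with a warning, and at least one
#' must be present.
#'
#' @param bulkExpr gene x sample expression matrix.
#' @param coreSet gene symbols to average (default [mhc1CoreSet()]).
#' @return named numeric vector, one score per sample.
#' @export
mhc1Score <- function(bulkExpr, coreSet = mhc1CoreSet()) {
    bulkExpr <- as.matrix(bulkExpr)
    present <- intersect(coreSet, rownames(bulkExpr))
    if (!length(present))
        stop("none of the core MHC-I genes are in the expression matrix")
    missing <- setdiff(coreSet, present)
    if (length(missing))
        warning("core MHC-I gene(s) missing, dropped: ",
                paste(missing, collapse = ", "))
    colMeans(bulkExpr[present, , drop = FALSE])
}

#' Cytolytic activity (CYT) score
#'
#' Per-sample geometric mean of the two key cytolytic effectors (GZMA and
#' PRF1 by default), with a small pseudocount guarding zeros:
#' sqrt((e1 + pc) * (e2 + pc)).
#'
#' @param bulkExpr gene x sample expression matrix (non-negative).
#' @param effectors two effector gene symbols.
#' @param pseudocount non-negative pseudocount (default 0.01).
#' @return named numeric vector of scores.
#' @examples
#' m <- matrix(c(4, 9), 2, 1, dimnames = list(c("GZMA", "PRF1"), "s1"))
#' cytScore(m, pseudocount = 0)  # 6
#' @export
cytScore <- function(bulkExpr, effectors = c("GZMA", "PRF1"),
                     pseudocount = 0.01) {
    bulkExpr <- as.matrix(bulkExpr)
    stopifnot(length(effectors) == 2L, pseudocount >= 0)
    miss <- setdiff(effectors, rownames(bulkExpr))
    if (length(miss))
        stop("effector gene(s) missing from the expression matrix: ",
             paste(miss, collapse = ", "))
    e <- bulkExpr[effectors, , drop = FALSE]
    if (min(e) < 0) stop("negative expression values")
    sqrt((e[1L, ] + pseudocount) * (e[2L, ] + pseudocount))
}
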