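#' Non-negative least-squares deconvolution of bulk profiles
#'
#' Estimates per-sample subtype abundances by solving, for each bulk
#' sample y, min ||S w - y||^2 subject to w >= 0 over the signature matrix
#' S (genes x subtypes), then normalizing the coefficients to sum to one.
#' Intended as a self-contained abundance estimator feeding
#' [stratifyBulk()]; externally computed abundance tables can be used in
#' its place.
#'
#' @param bulkExpr gene x sample matrix.
#' @param signatureMatrix gene x subtype profile matrix (full column rank
#'   over the shared genes).
#' @return samples x subtypes abundance matrix, rows summing to one.
#' @examples
#' S <- cbind(a = c(10, 0, 5), b = c(0, 10, 5))
#' rownames(S) <- paste0("g", 1:3)
#' y <- S %*% c(0.5, 0.5)
#' colnames(y) <- "s1"
#' nnlsDeconvolve(y, S)  # 0.5 / 0.5
#' @export
nnlsDeconvolve <- function(bulkExpr, signatureMatrix) {
    bulkExpr <- as.matrix(bulkExpr)
    S <- as.matrix(signatureMatrix)
    genes <- intersect(rownames(S), rownames(bulkExpr))
    if (length(genes) < ncol(S))
        stop("fewer shared informative genes (", length(genes),
             ") than subtypes (", ncol(S), ")")
    S <- S[genes, , drop = FALSE]
    if (qr(S)$rank < ncol(S))
        stop("signature matrix is rank-deficient over the shared genes")
    Y <- bulkExpr[genes, , drop = FALSE]
    W <- t(apply(Y, 2L, function(y) pracma::lsqnonneg(S, y)$x))
    W <- matrix(W, ncol = ncol(S),
                dimnames = list(colnames(bulkExpr), colnames(S)))
    tot <- rowSums(W)
    zero <- tot == 0
    if (any(zero)) {
        warning(sum(zero), " sample(s) with all-zero abundance left ",
                "unnormalized")
        tot[zero] <- 1
    }
    W / tot
}
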