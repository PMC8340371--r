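#' Remove genes with too many zero counts
#'
#' Sparse single-cell count matrices carry many dropout zeros; genes that
#' are zero in most cells contribute little to a proportionality network
#' and inflate its size. This keeps every gene whose fraction of zero
#' entries is at most `maxZeroFraction` (a gene with exactly the threshold
#' fraction is kept; removal requires strictly more zeros).
#'
#' @param expr genes x samples numeric matrix (or SummarizedExperiment).
#' @param maxZeroFraction largest tolerated fraction of zero entries per
#'   gene, default 0.25.
#' @return the row-subset expression matrix, gene order preserved.
#' @examples
#' m <- matrix(c(1, 0, 2, 3, 0, 0, 1, 2), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("gA", "gB"), paste0("c", 1:4)))
#' rownames(filterGenes(m, 0.25))  # gA kept (1/4 zeros), gB dropped (2/4)
#' @export
filterGenes <- function(expr, maxZeroFraction = 0.25) {
    m <- .expr_matrix(expr)
    if (nrow(m) == 0L || ncol(m) == 0L) stop("expression matrix is empty")
    if (maxZeroFraction < 0 || maxZeroFraction > 1)
        stop("maxZeroFraction must be in [0, 1]")
    zf <- rowMeans(m == 0)
    keep <- zf <= maxZeroFraction
    if (!any(keep))
        stop(sprintf(
            "no gene has a zero fraction <= %g; all %d genes removed",
            maxZeroFraction, nrow(m)))
    m[keep, , drop = FALSE]
}

#' Pairwise proportionality phi_s between genes
#'
#' For genes x and y observed across samples,
#' \eqn{\phi_s(x, y) = var(\log x - \log y) / var(\log x + \log y)}
#' (natural logs; the base cancels in the ratio). phi_s is 0 exactly when
#' the two genes are perfectly proportional and grows without bound as the
#' association weakens, making it a compositionally-coherent alternative to
#' correlation for sequencing counts. A `pseudocount` (default 1) is added
#' before the logs so zero counts are defined; values must be strictly
#' positive afterwards.
#'
#' Pairs with \eqn{var(\log x + \log y) = 0} have an undefined ratio; they
#' are assigned the largest finite phi_s observed in the matrix and a
#' warning is raised (if no pair is finite, an error).
#'
#' @param expr genes x samples numeric matrix, at least 2 genes and 3
#'   samples.
#' @param pseudocount nonnegative value added to every entry before logs.
#' @return a [ProportionalityMatrix-class].
#' @examples
#' m <- rbind(a = c(1, 2, 4), b = c(3, 6, 12), c = c(5, 1, 2))
#' colnames(m) <- paste0("s", 1:3)
#' phiS(proportionality(m, pseudocount = 0))["a", "b"]  # 0: b = 3 * a
#' @export
proportionality <- function(expr, pseudocount = 1) {
    m <- .expr_matrix(expr)
    if (nrow(m) < 2L) stop("need at least 2 genes")
    if (ncol(m) < 3L) stop("need at least 3 samples")
    if (pseudocount < 0) stop("pseudocount must be nonnegative")
    vals <- m + pseudocount
    if (any(vals <= 0))
        stop("values must be strictly positive after the pseudocount; ",
             "increase pseudocount")
    L <- log(vals)
    C <- stats::cov(t(L))                # gene-gene covariance of log values
    v <- diag(C)
    vsum <- outer(v, v, "+")
    num <- vsum - 2 * C
    den <- vsum + 2 * C
    num[num < 0] <- 0                    # clamp float round-off
    degen <- den <= 1e-12 & !diag(TRUE, nrow(m))
    phis <- matrix(0, nrow(m), nrow(m), dimnames = list(rownames(m),
                                                        rownames(m)))
    ok <- !degen
    phis[ok] <- num[ok] / den[ok]
    diag(phis) <- 0
    ndegen <- sum(degen) / 2L
    if (ndegen > 0) {
        finite_off <- phis[upper.tri(phis)][!degen[upper.tri(degen)]]
        if (length(finite_off) == 0L)
            stop("var(log x + log y) is zero for every gene pair; ",
                 "phi_s undefined")
        sentinel <- max(finite_off)
        phis[degen] <- sentinel
        warning(sprintf(
            "%d gene pair(s) had var(log x + log y) = 0; assigned the maximum finite phi_s (%s)",
            ndegen, format(sentinel)))
    }
    phis <- (phis + t(phis)) / 2         # enforce exact symmetry
    new("ProportionalityMatrix", phis = phis,
        provenance = list(pseudocount = pseudocount,
                          degeneratePairs = as.integer(ndegen)))
}

#' Max-scale phi_s dissimilarities to phi_i similarities
#'
#' \eqn{\phi_i = (\max\phi_s - \phi_s) / \max\phi_s}, with the maximum
#' taken over off-diagonal entries, so \eqn{\phi_i = 1} where
#' \eqn{\phi_s = 0} (perfect proportionality) and \eqn{\phi_i = 0} at the
#' least proportional pair observed. The map is affine and order-reversing.
#'
#' @param prop a [ProportionalityMatrix-class].
#' @return a [CoexpressionNetwork-class].
#' @export
toSimilarity <- function(prop) {
    stopifnot(is(prop, "ProportionalityMatrix"))
    phis <- prop@phis
    if (nrow(phis) < 2L) stop("need at least 2 genes")
    mx <- max(phis[upper.tri(phis)])
    if (mx <= 0)
        stop("max(phi_s) over off-diagonal entries is 0: all gene pairs ",
             "are perfectly proportional and the network is uninformative")
    phi <- (mx - phis) / mx
    diag(phi) <- 1
    new("CoexpressionNetwork", phi = phi, provenance = prop@provenance)
}

#' Build a co-expression network from expression counts
#'
#' Filters sparse genes, computes phi_s proportionality and max-scales it
#' to the phi_i similarity used as gene-gene edge weights. The network is
#' fully connected by construction (no sparsification); provenance records
#' the parameters and gene counts before/after filtering.
#'
#' @inheritParams filterGenes
#' @inheritParams proportionality
#' @return a [CoexpressionNetwork-class].
#' @examples
#' sim <- simulateExpression(syntheticSpec(seed = 7))
#' net <- buildCoexpressionNetwork(sim$expression[[1]])
#' net
#' @export
buildCoexpressionNetwork <- function(expr, maxZeroFraction = 0.25,
                                     pseudocount = 1) {
    m0 <- .expr_matrix(expr)
    m <- filterGenes(m0, maxZeroFraction)
    net <- toSimilarity(proportionality(m, pseudocount))
    net@provenance <- list(maxZeroFraction = maxZeroFraction,
                           pseudocount = pseudocount,
                           genesBefore = nrow(m0), genesAfter = nrow(m),
                           samples = ncol(m))
    net
}
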