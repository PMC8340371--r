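#' Restrict channel probabilities to the target nodes
#'
#' Only gene-annotation / gene-drug relationships are of interest, so the
#' gene-gene probabilities are excluded before scoring. The subvectors are
#' returned in target order and are deliberately not renormalised: the
#' centered log-ratio downstream is invariant to the subset's total.
#'
#' @param dist a [ChannelDistribution-class].
#' @param targetIds character vector of target node identifiers.
#' @return list with elements `pos` and `neg`, numeric vectors over targets.
#' @export
targetProbabilities <- function(dist, targetIds) {
    stopifnot(is(dist, "ChannelDistribution"))
    if (length(targetIds) == 0L) stop("target list is empty")
    if (!all(targetIds %in% names(dist@pPos)))
        stop("target id(s) not in the node set: ",
             paste(setdiff(targetIds, names(dist@pPos)), collapse = ", "))
    list(pos = dist@pPos[targetIds], neg = dist@pNeg[targetIds])
}

#' Centered log-ratio score of a probability vector
#'
#' \eqn{r_a = \log(p_a / g(p))} with \eqn{g(p)} the geometric mean
#' (natural log). Walk probabilities are compositional; the CLR makes them
#' comparable across reference genes and samples. Zeros are replaced by
#' half the smallest positive entry before the transform (multiplicative
#' replacement); an all-zero vector yields an all-zero score row with a
#' warning, and scoring is refused only when the vector is shorter than 2.
#'
#' @param p nonnegative numeric vector over at least 2 targets.
#' @param context label used in warnings (reference gene / channel).
#' @return numeric vector of scores summing to 0 (or all-zero for an
#'   all-zero input).
#' @examples
#' clrScore(c(0.2, 0.2, 0.4))
#' @export
clrScore <- function(p, context = "probability vector") {
    if (length(p) < 2L) stop("need at least 2 targets for a CLR")
    if (any(p < 0) || any(!is.finite(p)))
        stop("probabilities must be finite and nonnegative")
    if (all(p == 0)) {
        warning("all-zero ", context, ": emitting an all-zero score row")
        return(stats::setNames(numeric(length(p)), names(p)))
    }
    if (any(p == 0))
        p[p == 0] <- min(p[p > 0]) / 2
    lg <- log(p)
    lg - mean(lg)
}

#' Score every gene-target connection of a heterogeneous graph
#'
#' Runs the dual-channel walk for each reference gene, restricts the fixed
#' point to the target nodes and applies the CLR per channel, yielding two
#' genes x targets score matrices: `rPos` (up-regulation / association
#' evidence) and `rNeg` (down-regulation evidence). Genes whose walk fails
#' get NA rows and are listed in the `failed` slot.
#'
#' @param graph a [HeterogeneousGraph-class] with at least 2 targets.
#' @param cfg an [RwrConfig-class].
#' @param references gene nodes to score; default all.
#' @return an [RwrScoreMatrix-class].
#' @export
scoreAll <- function(graph, cfg = rwrConfig(), references = geneIds(graph)) {
    targets <- targetIds(graph)
    if (length(targets) < 2L) stop("graph needs at least 2 targets")
    walks <- walkAllReferences(graph, references, cfg)
    rp <- matrix(NA_real_, length(references), length(targets),
                 dimnames = list(references, targets))
    rn <- rp
    failed <- character()
    for (g in references) {
        w <- walks[[g]]
        if (!is(w, "ChannelDistribution")) {
            failed <- c(failed, g)
            next
        }
        tp <- targetProbabilities(w, targets)
        rp[g, ] <- suppressWarnings(
            clrScore(tp$pos, paste0("positive channel of '", g, "'")))
        rn[g, ] <- suppressWarnings(
            clrScore(tp$neg, paste0("negative channel of '", g, "'")))
    }
    if (length(failed))
        warning("walk failed for ", length(failed), " reference(s): ",
                paste(failed, collapse = ", "))
    new("RwrScoreMatrix", rPos = rp, rNeg = rn, failed = failed)
}
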