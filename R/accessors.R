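#' @rdname accessors
#' @export
setMethod("geneIds", "ProportionalityMatrix", function(x) rownames(x@phis))

#' @rdname accessors
#' @export
setMethod("geneIds", "CoexpressionNetwork", function(x) rownames(x@phi))

#' @rdname accessors
#' @export
setMethod("geneIds", "BipartiteGraph", function(x) rownames(x@weights))

#' @rdname accessors
#' @export
setMethod("geneIds", "HeterogeneousGraph",
    function(x) rownames(x@adjacency)[x@nodeKind == "gene"])

#' @rdname accessors
#' @export
setMethod("geneIds", "RwrScoreMatrix", function(x) rownames(x@rPos))

#' @rdname accessors
#' @export
setMethod("targetIds", "BipartiteGraph", function(x) colnames(x@weights))

#' @rdname accessors
#' @export
setMethod("targetIds", "HeterogeneousGraph",
    function(x) rownames(x@adjacency)[x@nodeKind == "target"])

#' @rdname accessors
#' @export
setMethod("targetIds", "RwrScoreMatrix", function(x) colnames(x@rPos))

#' @rdname accessors
#' @export
setMethod("phiS", "ProportionalityMatrix", function(x) x@phis)

#' @rdname accessors
#' @export
setMethod("phiI", "CoexpressionNetwork", function(x) x@phi)

#' @rdname accessors
#' @export
setMethod("weightMatrix", "BipartiteGraph", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("targetKind", "BipartiteGraph", function(x) x@targetKind)

#' @rdname accessors
#' @export
setMethod("targetKind", "HeterogeneousGraph", function(x) x@targetKind)

#' @rdname accessors
#' @export
setMethod("adjacencyMatrix", "HeterogeneousGraph", function(x) x@adjacency)

#' @rdname accessors
#' @export
setMethod("nodeIds", "HeterogeneousGraph", function(x) rownames(x@adjacency))

#' @rdname accessors
#' @export
setMethod("nodeIds", "TransitionModel", function(x) rownames(x@pos))

#' @rdname accessors
#' @export
setMethod("nodeKinds", "HeterogeneousGraph", function(x) x@nodeKind)

#' @rdname accessors
#' @export
setMethod("nodeKinds", "TransitionModel", function(x) x@nodeKind)

#' @rdname accessors
#' @export
setMethod("pPos", "ChannelDistribution", function(x) x@pPos)

#' @rdname accessors
#' @export
setMethod("pNeg", "ChannelDistribution", function(x) x@pNeg)

#' @rdname accessors
#' @export
setMethod("isConverged", "ChannelDistribution", function(x) x@converged)

#' @rdname accessors
#' @export
setMethod("scoresPos", "RwrScoreMatrix", function(x) x@rPos)

#' @rdname accessors
#' @export
setMethod("scoresNeg", "RwrScoreMatrix", function(x) x@rNeg)

#' @rdname accessors
#' @export
setMethod("provenance", "ProportionalityMatrix", function(x) x@provenance)

#' @rdname accessors
#' @export
setMethod("provenance", "CoexpressionNetwork", function(x) x@provenance)

setMethod("show", "ProportionalityMatrix", function(object) {
    cat("ProportionalityMatrix (phi_s) with", nrow(object@phis), "genes\n")
    off <- object@phis[upper.tri(object@phis)]
    if (length(off))
        cat(sprintf("  off-diagonal range: [%.4g, %.4g]\n",
                    min(off), max(off)))
})

setMethod("show", "CoexpressionNetwork", function(object) {
    cat("CoexpressionNetwork (phi_i) with", nrow(object@phi), "genes\n")
    if (length(object@provenance))
        cat("  provenance:", paste(names(object@provenance), collapse = ", "),
            "\n")
})

setMethod("show", "BipartiteGraph", function(object) {
    cat(sprintf("BipartiteGraph (%s): %d genes x %d targets, %d nonzero edges\n",
                object@targetKind, nrow(object@weights), ncol(object@weights),
                sum(object@weights != 0)))
})

setMethod("show", "HeterogeneousGraph", function(object) {
    cat(sprintf("HeterogeneousGraph: %d genes + %d %ss, %d negative edges\n",
                sum(object@nodeKind == "gene"),
                sum(object@nodeKind == "target"), object@targetKind,
                sum(object@adjacency < 0) / 2L))
})

setMethod("show", "TransitionModel", function(object) {
    cat(sprintf("TransitionModel over %d nodes (%d isolated)\n",
                nrow(object@pos),
                sum(rowSums(object@pos) + rowSums(object@neg) == 0)))
})

setMethod("show", "ChannelDistribution", function(object) {
    cat(sprintf(
        "ChannelDistribution for '%s': step %d, %sconverged (residual %.3g)\n",
        object@reference, object@step,
        if (object@converged) "" else "NOT ", object@residual))
    cat(sprintf("  mass: positive %.4f, negative %.4f\n",
                sum(object@pPos), sum(object@pNeg)))
})

setMethod("show", "RwrScoreMatrix", function(object) {
    cat(sprintf("RwrScoreMatrix: %d genes x %d targets (%d failed walks)\n",
                nrow(object@rPos), ncol(object@rPos), length(object@failed)))
})

setMethod("show", "RwrConfig", function(object) {
    cat(sprintf(
        "RwrConfig: alpha %.3g, maxSteps %d, tol %.3g, %s conservation\n",
        object@alpha, object@maxSteps, object@tol,
        if (object@jointConservation) "joint" else "per-channel"))
})

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(
        "SyntheticSpec: %d genes / %d modules, %d patients x %d cells (%d folds),\n",
        object@nGenes, object@nModules, object@nPatients,
        object@nCellsPerPatient, object@nFolds))
    cat(sprintf("  %d annotations, %d drugs x %d cell lines, seed %d\n",
                object@nAnnotations, object@nDrugs, object@nCellLines,
                object@seed))
})

setMethod("show", "AnovaResult", function(object) {
    cat(sprintf("AnovaResult: %d genes x %d targets, %d groups\n",
                nrow(object@pValues), ncol(object@pValues),
                length(unique(object@grouping))))
    cat(sprintf("  significant at gene-wise BH 0.05: %d cells\n",
                sum(object@fdrAdjusted < 0.05, na.rm = TRUE)))
})

setMethod("show", "SparsificationResult", function(object) {
    cat(sprintf(
        "SparsificationResult (level %.2f, replicate %d): hidden mean %.3f, unknown mean %.3f, p = %.3g\n",
        object@sparsityLevel, object@replicateId, mean(object@hiddenScores),
        mean(object@unknownScores), object@pValue))
})

setMethod("show", "AgreementMetrics", function(object) {
    cat(sprintf("AgreementMetrics (%s channel): spearman %.4f, MSE %.4f\n",
                object@channel, object@spearman, object@mse))
    cat("  top-k accuracy:",
        paste(sprintf("%s%%=%.4f", names(object@topKAccuracy),
                      object@topKAccuracy), collapse = ", "), "\n")
})
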