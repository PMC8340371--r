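#' @import methods
NULL

.check_square_symmetric <- function(m, what, lo = -Inf, hi = Inf) {
    msgs <- character()
    if (!is.matrix(m) || !is.numeric(m))
        return(sprintf("%s must be a numeric matrix", what))
    if (nrow(m) != ncol(m))
        msgs <- c(msgs, sprintf("%s must be square", what))
    if (is.null(rownames(m)) || is.null(colnames(m)) ||
        !identical(rownames(m), colnames(m)))
        msgs <- c(msgs, sprintf("%s must carry identical row/col names", what))
    if (anyDuplicated(rownames(m)))
        msgs <- c(msgs, sprintf("%s has duplicated identifiers", what))
    if (length(msgs) == 0L) {
        if (max(abs(m - t(m))) > 1e-8)
            msgs <- c(msgs, sprintf("%s must be symmetric", what))
        if (any(!is.finite(m)))
            msgs <- c(msgs, sprintf("%s has non-finite entries", what))
        else if (any(m < lo) || any(m > hi))
            msgs <- c(msgs, sprintf("%s has entries outside [%g, %g]", what, lo, hi))
    }
    msgs
}

#' ProportionalityMatrix: pairwise phi_s dissimilarities
#'
#' Symmetric gene-by-gene matrix of the proportionality metric
#' \eqn{\phi_s(x, y) = var(\log x - \log y) / var(\log x + \log y)},
#' a dissimilarity in \eqn{[0, \infty)} where 0 means the two genes are
#' perfectly proportional across samples. The diagonal is exactly 0.
#'
#' @slot phis symmetric nonnegative numeric matrix with gene identifiers as
#'   dimnames.
#' @slot provenance list of parameters recorded during construction
#'   (pseudocount, degenerate-pair count, ...).
#' @seealso [proportionality()], [toSimilarity()]
#' @export
setClass("ProportionalityMatrix",
    representation(phis = "matrix", provenance = "list"),
    prototype(provenance = list()))

setValidity("ProportionalityMatrix", function(object) {
    msgs <- .check_square_symmetric(object@phis, "phis", lo = 0)
    if (length(msgs) == 0L && nrow(object@phis) > 0L &&
        any(diag(object@phis) != 0))
        msgs <- c(msgs, "diagonal of phis must be exactly 0")
    if (length(msgs)) msgs else TRUE
})

#' CoexpressionNetwork: max-scaled gene-gene similarity
#'
#' Fully connected gene co-expression network whose edge weights are the
#' max-scaled similarity \eqn{\phi_i = (\max\phi_s - \phi_s)/\max\phi_s},
#' so \eqn{\phi_i \in [0, 1]} with 1 marking a perfectly proportional pair
#' and 0 the least proportional pair observed. The diagonal is 1
#' (self-similarity); it is dropped again before any random-walk transition
#' normalisation.
#'
#' @slot phi symmetric numeric matrix in \eqn{[0,1]} with gene dimnames.
#' @slot provenance list: filtering threshold, pseudocount, gene counts
#'   before/after filtering.
#' @seealso [buildCoexpressionNetwork()]
#' @export
setClass("CoexpressionNetwork",
    representation(phi = "matrix", provenance = "list"),
    prototype(provenance = list()))

setValidity("CoexpressionNetwork", function(object) {
    msgs <- .check_square_symmetric(object@phi, "phi", lo = 0, hi = 1)
    if (length(msgs) == 0L && nrow(object@phi) > 0L &&
        any(diag(object@phi) != 1))
        msgs <- c(msgs, "diagonal of phi must be exactly 1")
    if (length(msgs)) msgs else TRUE
})

#' BipartiteGraph: weighted gene-by-target incidence
#'
#' General-knowledge bipartite graph between genes and targets. For
#' `targetKind = "annotation"` the weights are binary membership indicators;
#' for `targetKind = "drug"` they are signed log2 fold changes, positive
#' meaning the drug up-regulates the gene.
#'
#' @slot weights numeric matrix, genes in rows, targets in columns, with
#'   dimnames.
#' @slot targetKind `"annotation"` or `"drug"`.
#' @export
setClass("BipartiteGraph",
    representation(weights = "matrix", targetKind = "character"))

setValidity("BipartiteGraph", function(object) {
    m <- object@weights
    msgs <- character()
    if (!is.matrix(m) || !is.numeric(m))
        msgs <- c(msgs, "weights must be a numeric matrix")
    else {
        if (is.null(rownames(m)) || is.null(colnames(m)))
            msgs <- c(msgs, "weights must carry gene and target identifiers")
        if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
            msgs <- c(msgs, "duplicate gene or target identifiers")
        if (any(!is.finite(m)))
            msgs <- c(msgs, "weights has non-finite entries")
    }
    if (length(object@targetKind) != 1L ||
        !object@targetKind %in% c("annotation", "drug"))
        msgs <- c(msgs, "targetKind must be 'annotation' or 'drug'")
    else if (identical(object@targetKind, "annotation") &&
             is.numeric(m) && !all(m %in% c(0, 1)))
        msgs <- c(msgs, "annotation graphs must have weights in {0, 1}")
    if (length(msgs)) msgs else TRUE
})

#' HeterogeneousGraph: joined signed gene/target adjacency
#'
#' Signed symmetric adjacency over genes followed by targets:
#' the gene-gene block is a co-expression similarity (all nonnegative), the
#' gene-target block holds bipartite weights (possibly negative), the
#' target-target block is zero, and the diagonal is zero (no self-loops).
#'
#' @slot adjacency symmetric numeric matrix with node identifiers.
#' @slot nodeKind character vector, `"gene"` or `"target"` per node.
#' @slot targetKind `"annotation"` or `"drug"`.
#' @seealso [joinGraphs()], [transitionModel()]
#' @export
setClass("HeterogeneousGraph",
    representation(adjacency = "matrix", nodeKind = "character",
                   targetKind = "character"))

setValidity("HeterogeneousGraph", function(object) {
    msgs <- .check_square_symmetric(object@adjacency, "adjacency")
    if (length(object@nodeKind) != nrow(object@adjacency))
        msgs <- c(msgs, "nodeKind length must match adjacency dimension")
    else if (!all(object@nodeKind %in% c("gene", "target")))
        msgs <- c(msgs, "nodeKind entries must be 'gene' or 'target'")
    if (length(msgs) == 0L) {
        if (any(diag(object@adjacency) != 0))
            msgs <- c(msgs, "diagonal must be zero (no self-loops)")
        tt <- object@nodeKind == "target"
        if (any(tt) && any(object@adjacency[tt, tt, drop = FALSE] != 0))
            msgs <- c(msgs, "target-target block must be zero")
        gg <- !tt
        if (any(gg) && any(object@adjacency[gg, gg, drop = FALSE] < 0))
            msgs <- c(msgs, "gene-gene block must be nonnegative")
    }
    if (length(msgs)) msgs else TRUE
})

#' TransitionModel: sign-split row-stochastic transitions
#'
#' Transition probabilities \eqn{P(x_j | x_i) = |e_{ij}| / \sum_l |e_{il}|}
#' of a signed heterogeneous graph, split by edge sign: `pos` carries the
#' within-channel transitions (nonnegative edges), `neg` the
#' channel-crossing transitions (negative edges). `pos + neg` is the
#' unsigned transition matrix; every row of a node with at least one
#' incident edge sums to 1, isolated nodes have all-zero rows. The model is
#' fixed for all steps of the walk.
#'
#' @slot pos,neg nonnegative numeric matrices with node dimnames.
#' @slot nodeKind character vector as in [HeterogeneousGraph-class].
#' @export
setClass("TransitionModel",
    representation(pos = "matrix", neg = "matrix", nodeKind = "character"))

setValidity("TransitionModel", function(object) {
    msgs <- character()
    if (!identical(dim(object@pos), dim(object@neg)))
        msgs <- c(msgs, "pos and neg must have identical dimensions")
    if (any(object@pos < 0) || any(object@neg < 0))
        msgs <- c(msgs, "transition probabilities must be nonnegative")
    if (length(msgs) == 0L) {
        rs <- rowSums(object@pos) + rowSums(object@neg)
        ok <- abs(rs - 1) <= 1e-12 | rs == 0
        if (!all(ok))
            msgs <- c(msgs, "non-isolated rows must sum to 1 within 1e-12")
    }
    if (length(msgs)) msgs else TRUE
})

#' ChannelDistribution: paired positive/negative probability vectors
#'
#' State of the dual-channel walk for one reference gene: `pPos[j]` is the
#' positive (up-regulation) information in node j, `pNeg[j]` the negative.
#' Under the joint-conservation convention the two channels together sum
#' to 1.
#'
#' @slot pPos,pNeg named nonnegative numeric vectors over all nodes.
#' @slot reference the reference node identifier.
#' @slot step number of update steps taken (the one-step neighbourhood
#'   distribution has step 2).
#' @slot converged logical; `FALSE` when the walk hit `maxSteps` before the
#'   L1 residual fell below tolerance.
#' @slot residual last L1 change of the stacked (pPos, pNeg) vector.
#' @export
setClass("ChannelDistribution",
    representation(pPos = "numeric", pNeg = "numeric", reference = "character",
                   step = "integer", converged = "logical",
                   residual = "numeric"))

setValidity("ChannelDistribution", function(object) {
    msgs <- character()
    if (length(object@pPos) != length(object@pNeg))
        msgs <- c(msgs, "pPos and pNeg must have equal length")
    if (any(object@pPos < 0) || any(object@pNeg < 0))
        msgs <- c(msgs, "channel probabilities must be nonnegative")
    if (length(msgs)) msgs else TRUE
})

#' RwrConfig: parameters of the restart walk
#'
#' @slot alpha restart probability in \eqn{[0,1]}; the default 0.1 weighs
#'   global graph structure over the local one-step neighbourhood.
#' @slot maxSteps hard cap on update steps (default 10000).
#' @slot tol L1 residual below which the walk is declared converged
#'   (default 1e-10).
#' @slot jointConservation when `TRUE` (default) the two channels jointly
#'   sum to 1; when `FALSE` each channel is renormalised to 1 after every
#'   restart mix.
#' @seealso [rwrConfig()]
#' @export
setClass("RwrConfig",
    representation(alpha = "numeric", maxSteps = "integer", tol = "numeric",
                   jointConservation = "logical"))

setValidity("RwrConfig", function(object) {
    msgs <- character()
    if (length(object@alpha) != 1L || object@alpha < 0 || object@alpha > 1)
        msgs <- c(msgs, "alpha must be a single value in [0, 1]")
    if (length(object@maxSteps) != 1L || object@maxSteps < 2L)
        msgs <- c(msgs, "maxSteps must be >= 2")
    if (length(object@tol) != 1L || object@tol < 0)
        msgs <- c(msgs, "tol must be nonnegative")
    if (length(msgs)) msgs else TRUE
})

#' RwrScoreMatrix: centered log-ratio walk scores per channel
#'
#' Gene-by-target matrices of CLR-transformed walk probabilities, one per
#' channel. Every finite row sums to 0 (the CLR property); rows of genes
#' whose walk failed are NA and listed in `failed`.
#'
#' @slot rPos,rNeg numeric matrices (genes x targets) with dimnames.
#' @slot failed character vector of reference genes whose walk failed.
#' @seealso [scoreAll()], [clrScore()]
#' @export
setClass("RwrScoreMatrix",
    representation(rPos = "matrix", rNeg = "matrix", failed = "character"),
    prototype(failed = character()))

setValidity("RwrScoreMatrix", function(object) {
    msgs <- character()
    if (!identical(dim(object@rPos), dim(object@rNeg)))
        msgs <- c(msgs, "rPos and rNeg must have identical dimensions")
    if (!identical(dimnames(object@rPos), dimnames(object@rNeg)))
        msgs <- c(msgs, "rPos and rNeg must share dimnames")
    if (length(msgs)) msgs else TRUE
})

#' SyntheticSpec: parameters of the synthetic-data generator
#'
#' Describes a synthetic study: genes grouped into proportional modules,
#' cells per patient, per-module annotations, signed per-module drug
#' responses across cell lines, and a fraction of genes whose module
#' membership is perturbed in one patient (the planted inter-patient
#' signal). Defaults are sized for minutes-scale runs: 60 genes in 6
#' modules, 5 patients x 40 cells, 12 annotations, 10 drugs, 5 cell lines.
#'
#' @slot nGenes,nCellsPerPatient,nPatients,nFolds,nModules,nAnnotations,nDrugs,nCellLines integer counts.
#' @slot moduleNoiseSd standard deviation (natural-log scale) of the
#'   multiplicative gene-level noise around the shared module signal.
#' @slot patientEffectFraction fraction of genes reassigned to another
#'   module in one randomly chosen patient.
#' @slot drugEffectMean,drugEffectSd mean magnitude and sd (log2 scale) of
#'   a drug's planted effect on its module.
#' @slot denseEffectSd sd (log2 scale) of the dense minor response a drug
#'   has on every gene; conserved across cell lines.
#' @slot lineEffectSd sd (log2 scale) of the per-line noise added to every
#'   drug signature.
#' @slot sharedEffectFraction fraction of drugs whose targeted module
#'   effect is identical across cell lines (the rest draw a line-specific
#'   sign and magnitude).
#' @slot offModuleRate probability that an annotation also links a gene
#'   outside its module.
#' @slot seed integer seed; all generator randomness flows from it.
#' @seealso [syntheticSpec()]
#' @export
setClass("SyntheticSpec",
    representation(nGenes = "integer", nCellsPerPatient = "integer",
                   nPatients = "integer", nFolds = "integer",
                   nModules = "integer", nAnnotations = "integer",
                   nDrugs = "integer", nCellLines = "integer",
                   moduleNoiseSd = "numeric",
                   patientEffectFraction = "numeric",
                   drugEffectMean = "numeric", drugEffectSd = "numeric",
                   denseEffectSd = "numeric", lineEffectSd = "numeric",
                   sharedEffectFraction = "numeric", offModuleRate = "numeric",
                   seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    msgs <- character()
    counts <- c(nGenes = object@nGenes, nCells = object@nCellsPerPatient,
                nPatients = object@nPatients, nFolds = object@nFolds,
                nModules = object@nModules, nAnnotations = object@nAnnotations,
                nDrugs = object@nDrugs, nCellLines = object@nCellLines)
    if (any(counts < 1L))
        msgs <- c(msgs, "all counts must be positive")
    if (object@nModules > object@nGenes)
        msgs <- c(msgs, "nModules must not exceed nGenes")
    for (f in c("patientEffectFraction", "sharedEffectFraction",
                "offModuleRate")) {
        v <- slot(object, f)
        if (v < 0 || v > 1) msgs <- c(msgs, paste(f, "must be in [0, 1]"))
    }
    if (object@moduleNoiseSd < 0 || object@drugEffectSd < 0 ||
        object@denseEffectSd < 0 || object@lineEffectSd < 0)
        msgs <- c(msgs, "noise standard deviations must be nonnegative")
    if (length(msgs)) msgs else TRUE
})

#' AnovaResult: per-connection inter-patient ANOVA
#'
#' One-way ANOVA of the walk score of every (gene, target) connection with
#' patient as the factor and per-patient folds as replicates, with
#' Benjamini-Hochberg adjustment applied gene-wise (within each gene's row
#' of target p-values).
#'
#' @slot pValues,fdrAdjusted,fStatistic numeric matrices (genes x targets).
#' @slot degenerate logical matrix marking cells where both the between-
#'   and within-group variance were zero (F undefined; p set to 1).
#' @slot grouping character vector of patient labels, one per observation.
#' @export
setClass("AnovaResult",
    representation(pValues = "matrix", fdrAdjusted = "matrix",
                   fStatistic = "matrix", degenerate = "matrix",
                   grouping = "character"))

setValidity("AnovaResult", function(object) {
    msgs <- character()
    p <- object@pValues; q <- object@fdrAdjusted
    if (!identical(dim(p), dim(q)))
        msgs <- c(msgs, "pValues and fdrAdjusted must match in shape")
    else {
        if (any(p < 0 | p > 1, na.rm = TRUE) || any(q < 0 | q > 1, na.rm = TRUE))
            msgs <- c(msgs, "p-values must lie in [0, 1]")
        if (any(q < p - 1e-12, na.rm = TRUE))
            msgs <- c(msgs, "adjusted p-values must not be below raw p-values")
    }
    if (length(msgs)) msgs else TRUE
})

#' SparsificationResult: one replicate of the link-hiding protocol
#'
#' @slot hiddenScores positive-channel scores at the hidden (1 -> 0) cells.
#' @slot unknownScores scores at never-linked cells.
#' @slot knownScores scores at retained links from the non-sparsified run.
#' @slot sparsityLevel fraction of links hidden.
#' @slot replicateId replicate index.
#' @slot tStatistic,pValue one-sided Welch t-test of hidden > unknown.
#' @export
setClass("SparsificationResult",
    representation(hiddenScores = "numeric", unknownScores = "numeric",
                   knownScores = "numeric", sparsityLevel = "numeric",
                   replicateId = "integer", tStatistic = "numeric",
                   pValue = "numeric"))

#' AgreementMetrics: imputed-vs-truth score agreement for one channel
#'
#' @slot spearman Spearman correlation over all flattened (gene, target)
#'   scores.
#' @slot mse mean squared error over the same cells.
#' @slot topKAccuracy named numeric: for each k in \{5, 10, 25, 50\}%, the
#'   fraction of the truth's top-k cells recovered among the imputed top-k.
#' @slot channel `"positive"` or `"negative"`.
#' @export
setClass("AgreementMetrics",
    representation(spearman = "numeric", mse = "numeric",
                   topKAccuracy = "numeric", channel = "character"))

setValidity("AgreementMetrics", function(object) {
    msgs <- character()
    if (!object@channel %in% c("positive", "negative"))
        msgs <- c(msgs, "channel must be 'positive' or 'negative'")
    if (any(object@topKAccuracy < 0 | object@topKAccuracy > 1, na.rm = TRUE))
        msgs <- c(msgs, "accuracies must lie in [0, 1]")
    if (length(msgs)) msgs else TRUE
})
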