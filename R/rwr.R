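#' Construct a walk configuration
#'
#' @param alpha restart probability in \eqn{[0,1]}; default 0.1 (more
#'   weight on global graph structure than on the one-step neighbourhood).
#' @param maxSteps hard cap on update steps, default 10000.
#' @param tol L1 residual for early stopping, default 1e-10.
#' @param jointConservation `TRUE` (default) keeps the joint mass of both
#'   channels at 1; `FALSE` renormalises each channel separately after
#'   every restart mix.
#' @return an [RwrConfig-class].
#' @export
rwrConfig <- function(alpha = 0.1, maxSteps = 10000L, tol = 1e-10,
                      jointConservation = TRUE) {
    new("RwrConfig", alpha = alpha, maxSteps = as.integer(maxSteps),
        tol = tol, jointConservation = jointConservation)
}

#' Sign-split transition model of a heterogeneous graph
#'
#' Normalises each node's absolute edge weights to transition
#' probabilities \eqn{P(x_j|x_i) = |e_{ij}| / \sum_{l} |e_{il}|} and splits
#' them by edge sign: nonnegative edges carry mass within a channel
#' (positive stays positive, negative stays negative), negative edges carry
#' mass across channels. Isolated nodes get all-zero rows and neither emit
#' nor receive mass. The model is fixed for all steps of the walk.
#'
#' @param graph a [HeterogeneousGraph-class].
#' @return a [TransitionModel-class].
#' @export
transitionModel <- function(graph) {
    stopifnot(is(graph, "HeterogeneousGraph"))
    adj <- adjacencyMatrix(graph)
    if (nrow(adj) < 2L) stop("graph needs at least 2 nodes")
    if (all(adj == 0)) stop("adjacency is all-zero; no walk possible")
    absadj <- abs(adj)
    rs <- rowSums(absadj)
    base <- absadj / ifelse(rs == 0, 1, rs)   # isolated rows stay zero
    pos <- base; pos[adj < 0] <- 0
    neg <- base; neg[adj >= 0] <- 0
    new("TransitionModel", pos = pos, neg = neg, nodeKind = nodeKinds(graph))
}

# Internal: positions/validation of reference nodes in a model.
.ref_index <- function(model, reference) {
    idx <- match(reference, nodeIds(model))
    if (anyNA(idx))
        stop("reference node(s) not in graph: ",
             paste(reference[is.na(idx)], collapse = ", "))
    out_deg <- rowSums(model@pos) + rowSums(model@neg)
    if (any(out_deg[idx] == 0))
        stop("reference node(s) isolated: ",
             paste(reference[out_deg[idx] == 0], collapse = ", "))
    idx
}

#' One-step neighbourhood distribution of a reference node
#'
#' Starts from unit positive mass on the reference node and applies one
#' sign-split propagation step. The result (step 2) is the local
#' distribution the walk restarts to: positive mass on neighbours reached
#' through nonnegative edges, negative mass on neighbours reached through
#' negative edges.
#'
#' @param model a [TransitionModel-class].
#' @param reference a node identifier.
#' @return a [ChannelDistribution-class] at step 2.
#' @export
initialDistribution <- function(model, reference) {
    stopifnot(is(model, "TransitionModel"), length(reference) == 1L)
    i <- .ref_index(model, reference)
    ids <- nodeIds(model)
    p0 <- numeric(length(ids)); names(p0) <- ids
    p0[i] <- 1
    d0 <- new("ChannelDistribution", pPos = p0,
              pNeg = stats::setNames(numeric(length(ids)), ids),
              reference = as.character(reference), step = 1L,
              converged = TRUE, residual = 0)
    propagate(model, d0)
}

#' One propagation step of the dual-channel walk
#'
#' Moves the paired probability vectors one step through the sign-split
#' transitions: positive mass over a nonnegative edge stays positive,
#' negative mass over a nonnegative edge stays negative, and either kind of
#' mass crossing a negative edge switches channel ("negative times negative
#' is positive"). The joint mass of the two channels is conserved whenever
#' no mass sits on an isolated node.
#'
#' @param model a [TransitionModel-class].
#' @param dist a [ChannelDistribution-class] over the model's nodes.
#' @return the propagated [ChannelDistribution-class] with `step + 1`.
#' @export
propagate <- function(model, dist) {
    stopifnot(is(model, "TransitionModel"), is(dist, "ChannelDistribution"))
    n <- nrow(model@pos)
    if (length(dist@pPos) != n)
        stop("distribution length does not match the model")
    pp <- drop(crossprod(model@pos, dist@pPos) +
               crossprod(model@neg, dist@pNeg))
    pn <- drop(crossprod(model@pos, dist@pNeg) +
               crossprod(model@neg, dist@pPos))
    names(pp) <- names(pn) <- nodeIds(model)
    initialize(dist, pPos = pp, pNeg = pn, step = dist@step + 1L)
}

# Internal batch engine: iterates all reference columns jointly.
# Returns list(pPos, pNeg: node x ref matrices; steps, converged, residual).
.walk_batch <- function(model, refs, cfg) {
    idx <- .ref_index(model, refs)
    n <- nrow(model@pos)
    ids <- nodeIds(model)
    E <- matrix(0, n, length(refs), dimnames = list(ids, refs))
    E[cbind(idx, seq_along(refs))] <- 1
    tpos <- t(model@pos); tneg <- t(model@neg)
    ## step 2: one propagation of the unit positive mass
    P2p <- tpos %*% E
    P2n <- tneg %*% E
    Qp <- P2p; Qn <- P2n
    step <- 2L
    resid <- rep(Inf, length(refs))
    a <- cfg@alpha
    repeat {
        if (step >= cfg@maxSteps) break
        Ap <- tpos %*% Qp + tneg %*% Qn
        An <- tpos %*% Qn + tneg %*% Qp
        Np <- (1 - a) * Ap + a * P2p
        Nn <- (1 - a) * An + a * P2n
        if (!cfg@jointConservation) {
            sp <- colSums(Np); sn <- colSums(Nn)
            Np <- sweep(Np, 2L, ifelse(sp == 0, 1, sp), "/")
            Nn <- sweep(Nn, 2L, ifelse(sn == 0, 1, sn), "/")
        }
        resid <- colSums(abs(Np - Qp)) + colSums(abs(Nn - Qn))
        Qp <- Np; Qn <- Nn
        step <- step + 1L
        if (max(resid) < cfg@tol) break
    }
    list(pPos = Qp, pNeg = Qn, step = step,
         converged = resid < cfg@tol, residual = resid)
}

#' Dual-channel random walk with restart for one reference gene
#'
#' Iterates the walk to its fixed point: each step propagates the current
#' distribution through the sign-split transitions and then mixes it with
#' the one-step neighbourhood distribution,
#' \eqn{P_{rst}(\cdot)_k = (1-\alpha) P(\cdot)_k + \alpha P(\cdot)_2},
#' for both channels. With `alpha = 1` the walk degenerates to the local
#' step-2 distribution. Iteration stops when the L1 change of the stacked
#' (pPos, pNeg) vector falls below `cfg@tol` or after `cfg@maxSteps` steps;
#' non-convergence is reported through the `converged` flag, not an error.
#'
#' @param model a [TransitionModel-class].
#' @param reference a node identifier (typically a gene).
#' @param cfg an [RwrConfig-class].
#' @return the fixed-point [ChannelDistribution-class].
#' @examples
#' adj <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("g1", "a1"),
#'                                                    c("g1", "a1")))
#' g <- new("HeterogeneousGraph", adjacency = adj,
#'          nodeKind = c("gene", "target"), targetKind = "annotation")
#' w <- walkWithRestart(transitionModel(g), "g1", rwrConfig())
#' pPos(w)  # (9/19, 10/19)
#' @export
walkWithRestart <- function(model, reference, cfg = rwrConfig()) {
    stopifnot(is(model, "TransitionModel"), length(reference) == 1L,
              is(cfg, "RwrConfig"))
    b <- .walk_batch(model, as.character(reference), cfg)
    new("ChannelDistribution",
        pPos = b$pPos[, 1L], pNeg = b$pNeg[, 1L],
        reference = as.character(reference), step = b$step,
        converged = b$converged[1L], residual = b$residual[1L])
}

#' Batch walk over many reference genes
#'
#' Runs [walkWithRestart()] for every reference on a shared transition
#' model. References are independent, so results do not depend on order;
#' a failure for one reference (e.g. an isolated node) is recorded and does
#' not abort the batch.
#'
#' @param graph a [HeterogeneousGraph-class].
#' @param references character vector of gene node identifiers; default all
#'   gene nodes.
#' @param cfg an [RwrConfig-class].
#' @return named list mapping each reference to its
#'   [ChannelDistribution-class], or to a condition object on failure.
#' @export
walkAllReferences <- function(graph, references = geneIds(graph),
                              cfg = rwrConfig()) {
    stopifnot(is(graph, "HeterogeneousGraph"))
    bad <- setdiff(references, geneIds(graph))
    if (length(bad))
        stop("references outside the gene node set: ",
             paste(bad, collapse = ", "))
    model <- transitionModel(graph)
    out_deg <- rowSums(model@pos) + rowSums(model@neg)
    ok <- references[out_deg[match(references, nodeIds(model))] > 0]
    res <- stats::setNames(vector("list", length(references)), references)
    for (r in setdiff(references, ok))
        res[[r]] <- simpleError(paste0("reference node(s) isolated: ", r))
    if (length(ok)) {
        b <- .walk_batch(model, ok, cfg)
        for (j in seq_along(ok))
            res[[ok[j]]] <- new("ChannelDistribution",
                                pPos = b$pPos[, j], pNeg = b$pNeg[, j],
                                reference = ok[j], step = b$step,
                                converged = b$converged[j],
                                residual = b$residual[j])
    }
    res
}
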