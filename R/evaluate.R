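#' Hide a fraction of annotation links ("sparsification")
#'
#' Turns 1s into 0s in a binary gene-annotation graph to test whether the
#' walk rediscovers them. Exactly `round(hideFraction * nLinks)` links are
#' hidden, sampled uniformly under the constraint that every gene and every
#' annotation retains at least one link (resampled up to `maxTries` times,
#' then an error). Deterministic given `seed`.
#'
#' @param bip an annotation-kind [BipartiteGraph-class] in which every row
#'   and column has at least one link.
#' @param hideFraction fraction of links to hide, in (0, 1).
#' @param seed integer seed.
#' @param maxTries bound on constraint resampling, default 1000.
#' @return list with `graph` (the sparsified [BipartiteGraph-class]) and
#'   `hiddenMask` (logical matrix marking the flipped cells).
#' @export
sparsifyGraph <- function(bip, hideFraction, seed, maxTries = 1000L) {
    stopifnot(is(bip, "BipartiteGraph"))
    if (targetKind(bip) != "annotation")
        stop("sparsification applies to annotation graphs")
    if (hideFraction <= 0 || hideFraction >= 1)
        stop("hideFraction must be in (0, 1)")
    w <- weightMatrix(bip)
    if (any(rowSums(w) == 0) || any(colSums(w) == 0))
        stop("every gene and every annotation must start with >= 1 link")
    links <- which(w == 1)
    nHide <- round(hideFraction * length(links))
    if (nHide < 1L) stop("hideFraction hides no link on this graph")
    hidden <- .with_seed(seed, {
        cand <- NULL
        ## uniform rejection sampling first: unbiased when the constraint
        ## is loose
        for (try in seq_len(maxTries)) {
            cc <- links[sample.int(length(links), nHide)]
            w2 <- w; w2[cc] <- 0
            if (all(rowSums(w2) >= 1) && all(colSums(w2) >= 1)) {
                cand <- cc
                break
            }
        }
        ## fall back to sequential sampling over currently-hideable links
        ## (rows/columns with >= 2 remaining links), which reaches the
        ## quota whenever it is reachable at all
        if (is.null(cand)) {
            for (try in seq_len(maxTries)) {
                w2 <- w
                picked <- integer()
                repeat {
                    if (length(picked) == nHide) break
                    rc <- rowSums(w2); cc2 <- colSums(w2)
                    elig <- links[w2[links] == 1 &
                                  rc[row(w2)[links]] > 1 &
                                  cc2[col(w2)[links]] > 1]
                    if (length(elig) == 0L) break
                    pick <- elig[sample.int(length(elig), 1L)]
                    w2[pick] <- 0
                    picked <- c(picked, pick)
                }
                if (length(picked) == nHide) {
                    cand <- picked
                    break
                }
            }
        }
        if (is.null(cand))
            stop("could not satisfy the >=1-link-per-row/column constraint ",
                 "in ", maxTries, " tries")
        cand
    })
    w[hidden] <- 0
    mask <- matrix(FALSE, nrow(w), ncol(w), dimnames = dimnames(w))
    mask[hidden] <- TRUE
    list(graph = new("BipartiteGraph", weights = w,
                     targetKind = "annotation"),
         hiddenMask = mask)
}

#' Random subset of a bipartite graph
#'
#' Keeps a uniform random `ceiling(fraction * n)` subset of genes and of
#' targets (used to bound the computational cost of the sparsification
#' protocol). Rows or columns left without any link are dropped with a
#' warning.
#'
#' @param bip a [BipartiteGraph-class].
#' @param geneFraction,targetFraction fractions in (0, 1].
#' @param seed integer seed.
#' @return the subset [BipartiteGraph-class].
#' @export
subsetBipartite <- function(bip, geneFraction, targetFraction, seed) {
    stopifnot(is(bip, "BipartiteGraph"))
    if (geneFraction <= 0 || geneFraction > 1 ||
        targetFraction <= 0 || targetFraction > 1)
        stop("fractions must be in (0, 1]")
    w <- weightMatrix(bip)
    keep <- .with_seed(seed, list(
        g = sort(sample(nrow(w), ceiling(geneFraction * nrow(w)))),
        t = sort(sample(ncol(w), ceiling(targetFraction * ncol(w))))))
    w <- w[keep$g, keep$t, drop = FALSE]
    emptyG <- rowSums(w != 0) == 0
    emptyT <- colSums(w != 0) == 0
    if (any(emptyG) || any(emptyT)) {
        warning("dropping ", sum(emptyG), " gene(s) and ", sum(emptyT),
                " target(s) left without links")
        w <- w[!emptyG, !emptyT, drop = FALSE]
    }
    if (nrow(w) == 0L || ncol(w) == 0L) stop("subset is empty")
    new("BipartiteGraph", weights = w, targetKind = targetKind(bip))
}

# Welch one-sided t-test (x > y), robust to constant groups. Groups of a
# single value cannot be tested (no within-group variance): NA statistics.
.welch_greater <- function(x, y) {
    if (length(x) < 1L || length(y) < 1L)
        stop("both groups must be nonempty")
    if (length(x) < 2L || length(y) < 2L)
        return(list(t = NA_real_, p = NA_real_))
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        d <- mean(x) - mean(y)
        return(list(t = if (d == 0) 0 else sign(d) * Inf,
                    p = if (d == 0) 0.5 else if (d > 0) 0 else 1))
    }
    ht <- stats::t.test(x, y, alternative = "greater", var.equal = FALSE)
    list(t = unname(ht$statistic), p = unname(ht$p.value))
}

#' Compare walk scores at hidden vs never-linked cells
#'
#' Collects positive-channel scores at the hidden (1 -> 0) cells and at the
#' never-linked ("unknown") cells of a sparsified annotation graph and
#' tests hidden > unknown with a one-sided Welch t-test. Rediscovery of
#' hidden links shows the walk finds real associations through the
#' co-expression graph.
#'
#' @param scores an [RwrScoreMatrix-class] from the sparsified graph.
#' @param hiddenMask logical matrix marking hidden cells.
#' @param zeroMask logical matrix marking cells with no link in the
#'   original (pre-sparsification) graph.
#' @return a [SparsificationResult-class] (level/replicate unset).
#' @export
hiddenVsUnknown <- function(scores, hiddenMask, zeroMask) {
    stopifnot(is(scores, "RwrScoreMatrix"))
    sp <- scoresPos(scores)
    if (!identical(dim(sp), dim(hiddenMask)) ||
        !identical(dim(sp), dim(zeroMask)))
        stop("mask dimensions do not match the score matrix")
    if (any(hiddenMask & zeroMask))
        stop("hidden and unknown masks must be disjoint")
    if (!any(hiddenMask) || !any(zeroMask)) stop("both masks must be nonempty")
    h <- sp[hiddenMask]; u <- sp[zeroMask]
    h <- h[is.finite(h)]; u <- u[is.finite(u)]
    ht <- .welch_greater(h, u)
    new("SparsificationResult", hiddenScores = h, unknownScores = u,
        knownScores = numeric(), sparsityLevel = NA_real_,
        replicateId = NA_integer_, tStatistic = ht$t, pValue = ht$p)
}

#' Link-sparsification rediscovery protocol
#'
#' For each sparsity level and replicate: subset the annotation graph (to
#' bound cost), hide a fraction of its links under the row/column
#' constraint, join the sparsified and the non-sparsified subset with the
#' co-expression network, score both, and compare hidden vs unknown cells.
#' The known-link scores of the non-sparsified run are retained for
#' reference. Fully deterministic given the master seed.
#'
#' @param bip the full annotation [BipartiteGraph-class].
#' @param net a [CoexpressionNetwork-class].
#' @param levels sparsity fractions, default `c(0.10, 0.25, 0.50)`.
#' @param nReplicates random graphs per level, default 25.
#' @param cfg an [RwrConfig-class].
#' @param seed master seed.
#' @param geneFraction,targetFraction subset fractions, default 0.25 each.
#' @return list of [SparsificationResult-class], one per level x replicate.
#' @export
runSparsificationProtocol <- function(bip, net,
                                      levels = c(0.10, 0.25, 0.50),
                                      nReplicates = 25L, cfg = rwrConfig(),
                                      seed = 1L, geneFraction = 0.25,
                                      targetFraction = 0.25) {
    out <- list()
    for (li in seq_along(levels)) {
        for (r in seq_len(nReplicates)) {
            s <- .child_seed(seed, li * 10000L + r)
            sub <- subsetBipartite(bip, geneFraction, targetFraction, s)
            sp <- sparsifyGraph(sub, levels[li], .child_seed(s, 1L))
            zeroMask <- weightMatrix(sub) == 0
            scSpars <- scoreAll(joinGraphs(net, sp$graph), cfg,
                                references = geneIds(sp$graph))
            scFull <- scoreAll(joinGraphs(net, sub), cfg,
                               references = geneIds(sub))
            res <- hiddenVsUnknown(scSpars, sp$hiddenMask, zeroMask)
            res@knownScores <-
                scoresPos(scFull)[weightMatrix(sub) == 1]
            res@sparsityLevel <- levels[li]
            res@replicateId <- as.integer(r)
            out[[length(out) + 1L]] <- res
        }
    }
    out
}

# Deterministic top-k cell selection: largest scores first, ties broken by
# (gene id, target id).
.top_cells <- function(m, k) {
    genes <- rownames(m)[row(m)]
    targets <- colnames(m)[col(m)]
    ord <- order(-as.vector(m), genes, targets)
    n <- max(1L, ceiling(k * length(m)))
    paste(genes, targets, sep = "\r")[ord[seq_len(n)]]
}

# Agreement for one channel's matrices.
.channel_agreement <- function(imp, tru, channel,
                               ks = c(0.05, 0.10, 0.25, 0.50)) {
    vi <- as.vector(imp); vt <- as.vector(tru)
    ok <- is.finite(vi) & is.finite(vt)
    acc <- vapply(ks, function(k) {
        ti <- .top_cells(imp, k); tt <- .top_cells(tru, k)
        length(intersect(ti, tt)) / length(tt)
    }, numeric(1))
    names(acc) <- as.character(ks * 100)
    new("AgreementMetrics",
        spearman = stats::cor(vi[ok], vt[ok], method = "spearman"),
        mse = mean((vi[ok] - vt[ok])^2),
        topKAccuracy = acc, channel = channel)
}

#' Agreement between imputed and ground-truth score matrices
#'
#' Per channel: Spearman correlation and mean squared error over all
#' flattened (gene, target) scores, and for each k in \{5, 10, 25, 50\}%
#' the overlap accuracy |top-k(imputed) intersect top-k(truth)| /
#' |top-k(truth)|, where top-k takes the k% largest scores of the channel
#' (ties broken deterministically by score, gene id, target id).
#'
#' @param imputed,truth [RwrScoreMatrix-class] objects over identical gene
#'   and target universes.
#' @return list with elements `positive` and `negative`, each an
#'   [AgreementMetrics-class].
#' @export
agreementMetrics <- function(imputed, truth) {
    stopifnot(is(imputed, "RwrScoreMatrix"), is(truth, "RwrScoreMatrix"))
    if (!identical(dimnames(scoresPos(imputed)), dimnames(scoresPos(truth))))
        stop("imputed and truth must share gene and target universes")
    list(positive = .channel_agreement(scoresPos(imputed), scoresPos(truth),
                                       "positive"),
         negative = .channel_agreement(scoresNeg(imputed), scoresNeg(truth),
                                       "negative"))
}

# Restrict a score matrix to given genes/targets.
.subset_scores <- function(x, genes, targets) {
    new("RwrScoreMatrix",
        rPos = scoresPos(x)[genes, targets, drop = FALSE],
        rNeg = scoresNeg(x)[genes, targets, drop = FALSE],
        failed = intersect(x@failed, genes))
}

#' Composite cross-cell-line drug-response validation
#'
#' Holds out one cell line: its own drug-response graph joined with its own
#' co-expression network gives the "ground truth" scores; the elementwise
#' average of the remaining lines' drug graphs joined with the held-out
#' line's network gives the imputed scores. High agreement shows that a
#' composite drug map generalises to an unseen cell type.
#'
#' @param drugGraphs named list, cell line -> drug [BipartiteGraph-class].
#' @param nets named list, cell line -> [CoexpressionNetwork-class].
#' @param heldOut name of the held-out cell line.
#' @param cfg an [RwrConfig-class].
#' @return list with `positive`/`negative` [AgreementMetrics-class] plus
#'   `imputed` and `truth` score matrices.
#' @export
runDrugValidation <- function(drugGraphs, nets, heldOut, cfg = rwrConfig()) {
    if (!heldOut %in% names(drugGraphs) || !heldOut %in% names(nets))
        stop("held-out cell line '", heldOut, "' missing from inputs")
    others <- drugGraphs[setdiff(names(drugGraphs), heldOut)]
    comp <- compositeGraph(unname(others))
    imput <- scoreAll(joinGraphs(nets[[heldOut]], comp), cfg)
    tru <- scoreAll(joinGraphs(nets[[heldOut]], drugGraphs[[heldOut]]), cfg)
    genes <- intersect(geneIds(imput), geneIds(tru))
    targets <- intersect(targetIds(imput), targetIds(tru))
    if (length(genes) == 0L || length(targets) == 0L)
        stop("imputed and truth runs share no cells")
    imput <- .subset_scores(imput, genes, targets)
    tru <- .subset_scores(tru, genes, targets)
    c(agreementMetrics(imput, tru), list(imputed = imput, truth = tru))
}

#' Per-connection inter-patient ANOVA of walk scores
#'
#' One-way ANOVA of each (gene, target) score with patient as the factor
#' and per-patient folds as replicates, computed in closed form over the
#' whole matrix, followed by gene-wise Benjamini-Hochberg adjustment (each
#' gene's row of target p-values is adjusted on its own). Cells with zero
#' between- and within-group variance have an undefined F; their p-value
#' is set to 1 and they are flagged in the `degenerate` slot.
#'
#' @param scoreStacks named list: patient -> list of
#'   [RwrScoreMatrix-class] (one per fold), all over identical universes.
#' @return an [AnovaResult-class].
#' @export
interPatientAnova <- function(scoreStacks) {
    if (length(scoreStacks) < 2L) stop("need at least 2 patients")
    nf <- vapply(scoreStacks, length, integer(1))
    if (any(nf < 2L)) stop("need at least 2 folds per patient")
    ref <- scoreStacks[[1L]][[1L]]
    dn <- dimnames(scoresPos(ref))
    flat <- list(); grouping <- character()
    for (p in names(scoreStacks)) {
        for (f in scoreStacks[[p]]) {
            stopifnot(identical(dimnames(scoresPos(f)), dn))
            flat[[length(flat) + 1L]] <- as.vector(scoresPos(f))
            grouping <- c(grouping, p)
        }
    }
    X <- do.call(cbind, flat)                # cells x observations
    n <- ncol(X)
    groups <- unique(grouping)
    P <- length(groups)
    grand <- rowMeans(X)
    ssb <- 0; ssw <- 0
    for (g in groups) {
        cols <- grouping == g
        m <- rowMeans(X[, cols, drop = FALSE])
        ssb <- ssb + sum(cols) * (m - grand)^2
        ssw <- ssw + rowSums((X[, cols, drop = FALSE] - m)^2)
    }
    df1 <- P - 1L; df2 <- n - P
    scale <- pmax(rowMeans(X^2), 1)
    zb <- ssb <= 1e-18 * scale
    zw <- ssw <= 1e-18 * scale
    f <- (ssb / df1) / (ssw / df2)
    pv <- stats::pf(f, df1, df2, lower.tail = FALSE)
    pv[zw & !zb] <- 0                        # perfect separation
    degen <- zb & zw
    pv[degen] <- 1
    f[degen] <- NA_real_
    toM <- function(v) matrix(v, length(dn[[1L]]), length(dn[[2L]]),
                              dimnames = dn)
    pm <- toM(pv)
    qm <- t(apply(pm, 1L, stats::p.adjust, method = "BH"))
    dimnames(qm) <- dn
    new("AnovaResult", pValues = pm, fdrAdjusted = qm, fStatistic = toM(f),
        degenerate = toM(degen), grouping = grouping)
}

#' Genes with the largest inter-patient score differences
#'
#' Ranks genes by the mean of their per-connection ANOVA F statistics
#' across targets (larger mean F = stronger patient effect) and returns the
#' top `n`; ties are broken lexicographically by gene id.
#'
#' @param scoreStacks as in [interPatientAnova()].
#' @param n number of genes to return.
#' @return character vector of gene identifiers.
#' @export
topVariableGenes <- function(scoreStacks, n) {
    an <- interPatientAnova(scoreStacks)
    f <- an@fStatistic
    stat <- apply(f, 1L, function(v) {
        v <- v[!is.na(v)]
        if (length(v) == 0L) -Inf else mean(v)
    })
    if (n > length(stat)) {
        warning("n exceeds the number of genes; returning all")
        n <- length(stat)
    }
    ids <- names(stat)
    ids[order(-stat, ids)][seq_len(n)]
}

#' Per-patient fold-wise score stacks for a cohort
#'
#' Convenience pipeline for the inter-patient analysis: filters genes on
#' the pooled cohort counts (so every patient fold shares one gene
#' universe), splits each patient's cells into folds, builds a phi_i
#' network per fold, joins it with the bipartite graph and scores all
#' genes.
#'
#' @param exprByPatient named list: patient -> genes x cells count matrix.
#' @param bip a [BipartiteGraph-class].
#' @param nFolds folds per patient, default 5.
#' @param cfg an [RwrConfig-class].
#' @param seed master seed for the fold splits.
#' @param maxZeroFraction cohort-level gene filter threshold, default 0.25.
#' @param pseudocount pseudocount for the log-ratio variances, default 1.
#' @return named list: patient -> list of [RwrScoreMatrix-class].
#' @export
cohortScoreStacks <- function(exprByPatient, bip, nFolds = 5L,
                              cfg = rwrConfig(), seed = 1L,
                              maxZeroFraction = 0.25, pseudocount = 1) {
    stopifnot(is.list(exprByPatient), length(exprByPatient) >= 2L)
    pooled <- do.call(cbind, lapply(exprByPatient, .expr_matrix))
    keep <- rownames(filterGenes(pooled, maxZeroFraction))
    keep <- intersect(keep, geneIds(bip))
    if (length(keep) < 2L) stop("fewer than 2 genes survive filtering")
    bip <- new("BipartiteGraph",
               weights = weightMatrix(bip)[keep, , drop = FALSE],
               targetKind = targetKind(bip))
    out <- list()
    for (pi in seq_along(exprByPatient)) {
        p <- names(exprByPatient)[pi]
        m <- .expr_matrix(exprByPatient[[pi]])[keep, , drop = FALSE]
        folds <- splitFolds(m, nFolds, .child_seed(seed, pi))
        out[[p]] <- lapply(folds, function(fm) {
            net <- toSimilarity(proportionality(fm, pseudocount))
            scoreAll(joinGraphs(net, bip), cfg, references = keep)
        })
    }
    out
}
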