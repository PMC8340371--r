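# Independent oracles and small fixture builders used across the suite.

# Build a HeterogeneousGraph from an explicit symmetric adjacency.
make_het <- function(adj, nGenes, targetKind = "annotation") {
    n <- nrow(adj)
    ids <- c(sprintf("g%d", seq_len(nGenes)),
             sprintf("t%d", seq_len(n - nGenes)))
    dimnames(adj) <- list(ids, ids)
    new("HeterogeneousGraph", adjacency = adj,
        nodeKind = c(rep("gene", nGenes), rep("target", n - nGenes)),
        targetKind = targetKind)
}

# Random connected signed heterogeneous graph: positive gene-gene block,
# signed gene-target block.
rand_signed_graph <- function(nGenes, nTargets, seed,
                              negProb = 0.5, density = 0.8) {
    withr::with_seed(seed, {
        n <- nGenes + nTargets
        adj <- matrix(0, n, n)
        gg <- matrix(stats::runif(nGenes^2, 0.1, 1), nGenes)
        gg[lower.tri(gg)] <- t(gg)[lower.tri(gg)]
        diag(gg) <- 0
        adj[seq_len(nGenes), seq_len(nGenes)] <- gg
        W <- matrix(stats::runif(nGenes * nTargets, 0.1, 1) *
                    (stats::runif(nGenes * nTargets) < density) *
                    ifelse(stats::runif(nGenes * nTargets) < negProb, -1, 1),
                    nGenes, nTargets)
        ## every target needs at least one edge
        for (j in seq_len(nTargets))
            if (all(W[, j] == 0)) W[sample.int(nGenes, 1L), j] <- 1
        adj[seq_len(nGenes), nGenes + seq_len(nTargets)] <- W
        adj[nGenes + seq_len(nTargets), seq_len(nGenes)] <- t(W)
        make_het(adj, nGenes, targetKind = "drug")
    })
}

# Direct linear-system solution of the dual-channel fixed point:
# q = (1 - alpha) M q + alpha q2 with M the stacked 2N transition map.
fixed_point_oracle <- function(model, reference, alpha) {
    tp <- t(model@pos); tn <- t(model@neg)
    n <- nrow(tp)
    M <- rbind(cbind(tp, tn), cbind(tn, tp))
    e <- numeric(n); e[match(reference, nodeIds(model))] <- 1
    q2 <- c(tp %*% e, tn %*% e)
    q <- unname(solve(diag(2 * n) - (1 - alpha) * M, alpha * q2))
    list(pPos = q[seq_len(n)], pNeg = q[n + seq_len(n)])
}

# Classic single-channel RWR by dense power iteration (restart to the
# one-step neighbourhood distribution, matching the dual-channel variant
# on all-positive graphs).
classic_rwr_oracle <- function(trans, reference, alpha, iters = 5000L) {
    tT <- t(trans)
    e <- numeric(nrow(trans)); e[reference] <- 1
    p2 <- drop(tT %*% e)
    p <- p2
    for (i in seq_len(iters)) p <- (1 - alpha) * drop(tT %*% p) + alpha * p2
    unname(p)
}

# Two-pass phi_s oracle: explicit per-pair variance computation.
phi_oracle <- function(mat, pseudocount = 1) {
    L <- log(mat + pseudocount)
    n <- nrow(mat)
    out <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        out[i, j] <- stats::var(L[i, ] - L[j, ]) /
            stats::var(L[i, ] + L[j, ])
    }
    out
}

# Expression fixture: two proportional blocks plus an unrelated gene.
toy_expression <- function(seed = 1, nCells = 30) {
    withr::with_seed(seed, {
        s1 <- exp(rnorm(nCells, 3, 1)); s2 <- exp(rnorm(nCells, 3, 1))
        m <- rbind(
            gA1 = s1 * 2, gA2 = s1 * 5, gA3 = s1 * 1.5,
            gB1 = s2 * 3, gB2 = s2 * 0.8,
            gC = exp(rnorm(nCells, 3, 1)))
        m <- round(m * exp(matrix(rnorm(length(m), 0, 0.1), nrow(m))))
        colnames(m) <- paste0("c", seq_len(nCells))
        m
    })
}
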