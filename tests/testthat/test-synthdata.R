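test_that("expression simulation is deterministic and module-structured", {
    spec <- syntheticSpec(seed = 7)
    sim <- simulateExpression(spec)
    expect_length(sim$expression, 5)
    expect_identical(dim(sim$expression$patient1), c(60L, 40L))
    expect_true(all(vapply(sim$expression, function(m)
        all(m >= 0 & m == round(m)), logical(1))))

    ## same seed identical, different seed different
    expect_identical(simulateExpression(spec)$expression,
                     sim$expression)
    expect_false(identical(
        simulateExpression(spec, seed = 8)$expression$patient1,
        sim$expression$patient1))

    ## within-module similarity beats between-module similarity
    net <- suppressWarnings(
        buildCoexpressionNetwork(do.call(cbind, sim$expression)))
    phi <- phiI(net)
    mods <- sim$modules[rownames(phi)]
    same <- outer(mods, mods, `==`) & upper.tri(phi)
    diff <- !outer(mods, mods, `==`) & upper.tri(phi)
    expect_gt(mean(phi[same]), mean(phi[diff]))

    ## noiseless modules are (near-)perfectly proportional; only count
    ## rounding separates them from phi_s = 0
    sim0 <- simulateExpression(syntheticSpec(seed = 7, moduleNoiseSd = 0,
                                             patientEffectFraction = 0))
    p0 <- suppressWarnings(
        proportionality(sim0$expression$patient1, pseudocount = 1))
    mods0 <- sim0$modules
    same0 <- outer(mods0, mods0, `==`) & upper.tri(phiS(p0))
    expect_lt(mean(phiS(p0)[same0]), 0.01)

    ## planted reassignments land in the stated patient
    expect_identical(nrow(sim$reassignments), 3L)  # 5% of 60 genes
    for (i in seq_len(nrow(sim$reassignments))) {
        g <- sim$reassignments$gene[i]
        p <- sim$reassignments$patient[i]
        expect_false(sim$reassignments$module[i] == sim$modules[g])
    }
})

test_that("annotation simulation covers every gene and annotation", {
    spec <- syntheticSpec(seed = 19)
    ann <- simulateAnnotations(spec)
    w <- weightMatrix(ann$graph)
    expect_identical(dim(w), c(60L, 12L))
    expect_true(all(rowSums(w) >= 1))
    expect_true(all(colSums(w) >= 1))
    ## each annotation contains its full module
    base <- rep_len(seq_len(spec@nModules), spec@nGenes)
    for (a in seq_len(12))
        expect_true(all(w[base == ann$moduleOf[a], a] == 1))
    ## off-module link rate is near the requested 5% (binomial error)
    off <- vapply(seq_len(12), function(a)
        mean(w[base != ann$moduleOf[a], a]), numeric(1))
    expect_lt(abs(mean(off) - 0.05), 0.03)
    expect_identical(simulateAnnotations(spec)$graph, ann$graph)
})

test_that("drug simulation plants signed module responses with shared structure", {
    spec <- syntheticSpec(seed = 23, nDrugs = 6, nCellLines = 3)
    dr <- simulateDrugResponses(spec)
    expect_length(dr$lines, 3)
    expect_length(dr$lines$line1$treated, 6)

    g1 <- drugResponseGraph(dr$lines$line1$treated, dr$lines$line1$naive)
    w <- weightMatrix(g1)
    base <- rep_len(seq_len(spec@nModules), spec@nGenes)
    eff <- dr$effects[dr$effects$line == "line1", ]
    ## estimated module-level log-FC tracks the planted sign and size
    for (d in seq_len(6)) {
        est <- median(w[base == eff$module[d], d])
        expect_equal(sign(est), sign(eff$effect[d]))
        expect_lt(abs(est - eff$effect[d]), 1)
    }
    ## a zero-effect drug has log-FC near zero: check off-module genes
    offw <- w[base != eff$module[1], 1]
    planted_off <- dr$effectMatrices$line1[base != eff$module[1], 1]
    expect_lt(median(abs(offw - planted_off)), 0.3)

    ## shared drugs correlate across lines more than line-specific ones
    cors <- vapply(seq_len(6), function(d)
        cor(dr$effectMatrices$line1[, d], dr$effectMatrices$line2[, d]),
        numeric(1))
    shared <- dr$effects$shared[dr$effects$line == "line1"]
    expect_gt(min(cors[shared]), max(0.5, mean(cors[!shared])))

    expect_identical(simulateDrugResponses(spec)$effectMatrices,
                     dr$effectMatrices)
})

test_that("fold splitting partitions cells into near-equal parts", {
    m <- matrix(1, 3, 97, dimnames = list(paste0("g", 1:3),
                                          paste0("c", 1:97)))
    folds <- splitFolds(m, 5, seed = 3)
    expect_identical(sort(vapply(folds, ncol, integer(1)),
                          decreasing = TRUE),
                     c(20L, 20L, 19L, 19L, 19L))
    cells <- unlist(lapply(folds, colnames))
    expect_identical(sort(cells), sort(colnames(m)))
    expect_identical(anyDuplicated(cells), 0L)
    expect_identical(lapply(splitFolds(m, 5, seed = 3), colnames),
                     lapply(folds, colnames))
    expect_false(identical(lapply(splitFolds(m, 5, seed = 4), colnames),
                           lapply(folds, colnames)))
    expect_error(splitFolds(m, 98, 1), "nFolds")
})
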