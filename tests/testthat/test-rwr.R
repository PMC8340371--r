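# 3-node toy used throughout: node 1 with edges e12 = +2, e13 = -1.
toy3 <- function() {
    adj <- matrix(c(0, 2, -1,
                    2, 0, 0,
                    -1, 0, 0), 3, 3, byrow = TRUE)
    make_het(adj, 1, targetKind = "drug")
}

test_that("transition rows normalise absolute weights and split by sign", {
    tm <- transitionModel(toy3())
    base <- tm@pos + tm@neg
    expect_equal(unname(base[1, ]), c(0, 2/3, 1/3))
    expect_equal(unname(tm@pos[1, ]), c(0, 2/3, 0))
    expect_equal(unname(tm@neg[1, ]), c(0, 0, 1/3))

    ## all-positive graph: neg mask identically zero
    tmpos <- transitionModel(rand_signed_graph(6, 3, 2, negProb = 0))
    expect_true(all(tmpos@neg == 0))

    ## random signed 8-node graph vs independent row-normalisation oracle
    het <- rand_signed_graph(5, 3, seed = 6)
    tm2 <- transitionModel(het)
    adj <- adjacencyMatrix(het)
    oracle <- abs(adj) / rowSums(abs(adj))
    expect_equal(unname(tm2@pos + tm2@neg), unname(oracle),
                 tolerance = 1e-14)
    expect_equal(unname(rowSums(tm2@pos + tm2@neg)),
                 rep(1, 8), tolerance = 1e-12)
    expect_true(all((tm2@pos > 0) == (adj > 0)))
    expect_true(all((tm2@neg > 0) == (adj < 0)))

    allzero <- matrix(0, 2, 2)
    expect_error(transitionModel(make_het(allzero, 1)), "all-zero")
})

test_that("the step-2 distribution is one split propagation from the reference", {
    tm <- transitionModel(toy3())
    d <- initialDistribution(tm, "g1")
    expect_equal(unname(pPos(d)), c(0, 2/3, 0))
    expect_equal(unname(pNeg(d)), c(0, 0, 1/3))
    expect_identical(d@step, 2L)

    ## two-node positive graph
    two <- make_het(matrix(c(0, 1, 1, 0), 2), 1)
    d2 <- initialDistribution(transitionModel(two), "g1")
    expect_equal(unname(pPos(d2)), c(0, 1))
    expect_equal(unname(pNeg(d2)), c(0, 0))

    ## star: hub with equal positive edges to 4 leaves
    star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star[2:5, 1] <- 1
    ds <- initialDistribution(transitionModel(make_het(star, 1)), "g1")
    expect_equal(unname(pPos(ds)), c(0, rep(0.25, 4)))

    expect_error(initialDistribution(tm, "nope"), "not in graph")
    iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
    expect_error(initialDistribution(transitionModel(make_het(iso, 2)),
                                     "t1"), "isolated")
})

test_that("propagation follows the sign algebra and conserves joint mass", {
    tm <- transitionModel(toy3())
    ids <- nodeIds(tm)
    mk <- function(pp, pn) new("ChannelDistribution",
        pPos = stats::setNames(pp, ids), pNeg = stats::setNames(pn, ids),
        reference = "g1", step = 1L, converged = TRUE, residual = 0)

    ## positive mass through +/- edges splits into the two channels
    d1 <- propagate(tm, mk(c(1, 0, 0), c(0, 0, 0)))
    expect_equal(unname(pPos(d1)), c(0, 2/3, 0))
    expect_equal(unname(pNeg(d1)), c(0, 0, 1/3))

    ## negative mass crossing a negative edge becomes positive
    d2 <- propagate(tm, mk(c(0, 0, 0), c(0, 0, 1)))
    expect_equal(unname(pPos(d2)), c(1, 0, 0))
    expect_equal(unname(pNeg(d2)), c(0, 0, 0))

    ## joint conservation over 50 steps on a random signed graph
    het <- rand_signed_graph(5, 3, seed = 13)
    tmr <- transitionModel(het)
    d <- initialDistribution(tmr, "g2")
    for (i in 1:50) {
        d <- propagate(tmr, d)
        expect_equal(sum(pPos(d)) + sum(pNeg(d)), 1, tolerance = 1e-10)
    }
})

test_that("the restart walk reaches the analytic fixed point", {
    two <- make_het(matrix(c(0, 1, 1, 0), 2), 1)
    tm <- transitionModel(two)
    w <- walkWithRestart(tm, "g1", rwrConfig(alpha = 0.1))
    expect_equal(unname(pPos(w)), c(9/19, 10/19), tolerance = 1e-10)
    expect_equal(unname(pNeg(w)), c(0, 0))
    expect_true(isConverged(w))

    ## alpha = 1 degenerates to the step-2 distribution
    w1 <- walkWithRestart(tm, "g1", rwrConfig(alpha = 1))
    expect_equal(pPos(w1), pPos(initialDistribution(tm, "g1")))

    ## all-positive graph: classic single-channel RWR oracle, p_neg == 0
    het <- rand_signed_graph(6, 4, seed = 3, negProb = 0)
    tmp <- transitionModel(het)
    wp <- walkWithRestart(tmp, "g3", rwrConfig())
    expect_true(all(pNeg(wp) == 0))
    oracle <- classic_rwr_oracle(tmp@pos + tmp@neg,
                                 match("g3", nodeIds(tmp)), 0.1)
    expect_equal(unname(pPos(wp)), oracle, tolerance = 1e-8)

    ## non-convergence returns the last iterate with the flag unset
    wshort <- walkWithRestart(tm, "g1", rwrConfig(maxSteps = 3))
    expect_false(isConverged(wshort))
    expect_s4_class(wshort, "ChannelDistribution")
})

test_that("signed fixed points match the stacked linear-system oracle", {
    for (s in 1:10) {
        nG <- sample(3:6, 1)
        nT <- sample(2:4, 1)
        het <- rand_signed_graph(nG, nT, seed = 100 + s)
        tm <- transitionModel(het)
        ref <- sprintf("g%d", sample.int(nG, 1))
        w <- walkWithRestart(tm, ref, rwrConfig())
        oracle <- fixed_point_oracle(tm, ref, 0.1)
        expect_equal(unname(pPos(w)), oracle$pPos, tolerance = 1e-8)
        expect_equal(unname(pNeg(w)), oracle$pNeg, tolerance = 1e-8)
    }
})

test_that("sign flips on gene-target edges swap the target channels", {
    het <- rand_signed_graph(5, 3, seed = 21, negProb = 0)
    adj <- adjacencyMatrix(het)
    flip <- adj
    tt <- nodeKinds(het) == "target"
    flip[!tt, tt] <- -flip[!tt, tt]
    flip[tt, !tt] <- -flip[tt, !tt]
    hetf <- new("HeterogeneousGraph", adjacency = flip,
                nodeKind = nodeKinds(het), targetKind = "drug")
    w0 <- walkWithRestart(transitionModel(het), "g1", rwrConfig())
    wf <- walkWithRestart(transitionModel(hetf), "g1", rwrConfig())
    expect_equal(pPos(w0)[tt], pNeg(wf)[tt], tolerance = 1e-9)
    expect_equal(pNeg(w0)[tt], pPos(wf)[tt], tolerance = 1e-9)
})

test_that("batch walks equal single walks and tolerate per-gene failures", {
    het <- rand_signed_graph(5, 3, seed = 31)
    tm <- transitionModel(het)
    refs <- sprintf("g%d", 1:5)
    batch <- walkAllReferences(het, refs, rwrConfig())
    for (r in refs)
        expect_equal(pPos(batch[[r]]),
                     pPos(walkWithRestart(tm, r, rwrConfig())),
                     tolerance = 1e-9)

    ## automorphism: two leaves of a symmetric star swap cleanly
    star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star[2:4, 1] <- 1
    hstar <- make_het(star, 3)
    b <- walkAllReferences(hstar, c("g2", "g3"), rwrConfig())
    p2 <- pPos(b$g2); p3 <- pPos(b$g3)
    expect_equal(unname(p2[c("g1", "g2", "g3", "t1")]),
                 unname(p3[c("g1", "g3", "g2", "t1")]), tolerance = 1e-12)

    ## an isolated reference is recorded, not fatal
    adj <- adjacencyMatrix(het)
    adj["g5", ] <- 0; adj[, "g5"] <- 0
    hiso <- new("HeterogeneousGraph", adjacency = adj,
                nodeKind = nodeKinds(het), targetKind = "drug")
    biso <- walkAllReferences(hiso, c("g1", "g5"), rwrConfig())
    expect_s4_class(biso$g1, "ChannelDistribution")
    expect_s3_class(biso$g5, "simpleError")
    expect_error(walkAllReferences(het, "zzz"), "outside")
})
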