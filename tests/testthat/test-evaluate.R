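mk_ann <- function(w) new("BipartiteGraph", weights = w,
                          targetKind = "annotation")

test_that("sparsification hides an exact count and never empties a row or column", {
    spec <- syntheticSpec(seed = 61)
    ann <- simulateAnnotations(spec)$graph
    L <- sum(weightMatrix(ann))
    sp <- sparsifyGraph(ann, 0.10, seed = 9)
    expect_identical(sum(sp$hiddenMask), as.integer(round(0.10 * L)))
    expect_equal(sum(weightMatrix(sp$graph)), L - round(0.10 * L))
    expect_true(all(rowSums(weightMatrix(sp$graph)) >= 1))
    expect_true(all(colSums(weightMatrix(sp$graph)) >= 1))
    ## flipped cells were links
    expect_true(all(weightMatrix(ann)[sp$hiddenMask] == 1))

    ## heavier sparsification still honours the constraint
    sp50 <- sparsifyGraph(ann, 0.50, seed = 9)
    expect_identical(sum(sp50$hiddenMask), as.integer(round(0.50 * L)))
    expect_true(all(rowSums(weightMatrix(sp50$graph)) >= 1))
    expect_true(all(colSums(weightMatrix(sp50$graph)) >= 1))

    ## an annotation with a single link never loses it
    w <- matrix(0, 4, 2, dimnames = list(paste0("g", 1:4), c("a1", "a2")))
    w[, 1] <- 1; w[4, 2] <- 1
    for (s in 1:20) {
        spx <- sparsifyGraph(mk_ann(w), 0.2, seed = s)
        expect_equal(weightMatrix(spx$graph)[4, "a2"], 1)
    }

    ## seeded determinism; different seeds give different masks
    expect_identical(sparsifyGraph(ann, 0.25, seed = 3)$hiddenMask,
                     sparsifyGraph(ann, 0.25, seed = 3)$hiddenMask)
    expect_false(identical(sparsifyGraph(ann, 0.25, seed = 3)$hiddenMask,
                           sparsifyGraph(ann, 0.25, seed = 4)$hiddenMask))

    expect_error(sparsifyGraph(ann, 0, 1), "hideFraction")
    drug <- new("BipartiteGraph", weights = weightMatrix(ann),
                targetKind = "drug")
    expect_error(sparsifyGraph(drug, 0.1, 1), "annotation")
})

test_that("bipartite subsetting uses ceiling counts and drops empty rows", {
    spec <- syntheticSpec(seed = 62, nGenes = 40, nModules = 4,
                          nAnnotations = 20)
    ann <- simulateAnnotations(spec)$graph
    sub <- suppressWarnings(subsetBipartite(ann, 0.25, 0.25, seed = 2))
    expect_lte(nrow(weightMatrix(sub)), 10)
    expect_lte(ncol(weightMatrix(sub)), 5)
    expect_true(all(rowSums(weightMatrix(sub) != 0) >= 1))

    ## identity at (1, 1)
    idt <- subsetBipartite(ann, 1, 1, seed = 7)
    expect_equal(weightMatrix(idt), weightMatrix(ann))

    ## seeded determinism
    expect_equal(
        weightMatrix(suppressWarnings(subsetBipartite(ann, .5, .5, 11))),
        weightMatrix(suppressWarnings(subsetBipartite(ann, .5, .5, 11))))
})

test_that("hidden-vs-unknown comparison behaves at the null and under separation", {
    rp <- matrix(2, 3, 4, dimnames = list(paste0("g", 1:3),
                                          paste0("a", 1:4)))
    sc <- new("RwrScoreMatrix", rPos = rp, rNeg = rp * 0)
    hid <- rp == 99; hid[1, 1:2] <- TRUE; hid[2, 1] <- TRUE
    unk <- rp == 99; unk[3, 3:4] <- TRUE; unk[2, 4] <- TRUE
    r0 <- hiddenVsUnknown(sc, hid, unk)
    expect_equal(r0@tStatistic, 0)
    expect_equal(r0@pValue, 0.5)

    rp2 <- rp; rp2[hid] <- 2 + rnorm(3, 0, 1e-8); rp2[unk] <- rnorm(3, 0, 1e-8)
    sc2 <- new("RwrScoreMatrix", rPos = rp2, rNeg = rp2 * 0)
    r1 <- hiddenVsUnknown(sc2, hid, unk)
    expect_lt(r1@pValue, 1e-6)

    expect_error(hiddenVsUnknown(sc, hid, hid), "disjoint")
    expect_error(hiddenVsUnknown(sc, hid & FALSE, unk), "nonempty")
})

test_that("agreement metrics are perfect on identity and antitone on negation", {
    m <- withr::with_seed(71, matrix(rnorm(60), 6, 10,
        dimnames = list(paste0("g", 1:6), paste0("d", 1:10))))
    sc <- new("RwrScoreMatrix", rPos = m, rNeg = -m / 2)
    ag <- agreementMetrics(sc, sc)
    expect_equal(ag$positive@spearman, 1)
    expect_equal(ag$positive@mse, 0)
    expect_true(all(ag$positive@topKAccuracy == 1))
    expect_identical(names(ag$positive@topKAccuracy),
                     c("5", "10", "25", "50"))

    neg <- new("RwrScoreMatrix", rPos = -m, rNeg = m / 2)
    agn <- agreementMetrics(neg, sc)
    expect_equal(agn$positive@spearman, -1)

    ## top-k accuracy of independent random rankings is ~k in expectation
    accs <- vapply(1:100, function(s) withr::with_seed(s, {
        a <- matrix(rnorm(1000), 40, 25, dimnames = list(paste0("g", 1:40),
                                                         paste0("d", 1:25)))
        b <- matrix(rnorm(1000), 40, 25, dimnames = dimnames(a))
        agreementMetrics(new("RwrScoreMatrix", rPos = a, rNeg = a),
                         new("RwrScoreMatrix", rPos = b, rNeg = b)
                         )$positive@topKAccuracy[["10"]]
    }), numeric(1))
    se <- stats::sd(accs) / 10
    expect_lt(abs(mean(accs) - 0.10), 3 * se + 1e-12)

    bad <- new("RwrScoreMatrix", rPos = m[, 1:5], rNeg = m[, 1:5])
    expect_error(agreementMetrics(sc, bad), "universes")
})

test_that("the drug-validation protocol is perfect when every line shares one graph", {
    spec <- syntheticSpec(seed = 81, nDrugs = 8)
    dr <- simulateDrugResponses(spec)
    nets <- lapply(dr$lines[1:3],
                   function(l) suppressWarnings(
                       buildCoexpressionNetwork(l$naive)))
    shared <- drugResponseGraph(dr$lines$line1$treated,
                                dr$lines$line1$naive)
    graphs <- list(line1 = shared, line2 = shared, line3 = shared)
    v <- runDrugValidation(graphs, nets, "line3", rwrConfig())
    expect_equal(v$positive@spearman, 1, tolerance = 1e-8)
    expect_lt(v$positive@mse, 1e-12)
    expect_true(all(v$positive@topKAccuracy == 1))

    ## holding out a different line changes the result (no leakage)
    graphs2 <- lapply(dr$lines[1:3], function(l)
        drugResponseGraph(l$treated, l$naive))
    v1 <- runDrugValidation(graphs2, nets, "line1", rwrConfig())
    v2 <- runDrugValidation(graphs2, nets, "line2", rwrConfig())
    expect_false(isTRUE(all.equal(v1$positive@spearman,
                                  v2$positive@spearman)))
    expect_error(runDrugValidation(graphs2, nets, "lineX"), "missing")
})

test_that("the sparsification protocol enumerates levels x replicates deterministically", {
    spec <- syntheticSpec(seed = 91)
    sim <- simulateExpression(spec)
    ann <- simulateAnnotations(spec)$graph
    net <- suppressWarnings(
        buildCoexpressionNetwork(do.call(cbind, sim$expression)))
    run <- function() suppressWarnings(suppressMessages(
        runSparsificationProtocol(ann, net, levels = c(0.10, 0.25),
                                  nReplicates = 3, seed = 17,
                                  geneFraction = 1, targetFraction = 1)))
    res <- run()
    expect_length(res, 6)
    expect_equal(vapply(res, slot, numeric(1), "sparsityLevel"),
                 rep(c(0.10, 0.25), each = 3))
    ## known-link scores from the non-sparsified run are retained
    expect_true(all(vapply(res, function(r)
        length(r@knownScores) > 0, logical(1))))
    ## end-to-end determinism under the master seed
    res2 <- run()
    expect_identical(lapply(res, slot, "hiddenScores"),
                     lapply(res2, slot, "hiddenScores"))
    expect_identical(lapply(res, slot, "pValue"),
                     lapply(res2, slot, "pValue"))
})

test_that("the matrix ANOVA matches aov and controls the null", {
    ## stacks with no patient effect: nothing significant, and the
    ## closed-form F agrees with stats::aov cell by cell
    dn <- list(paste0("g", 1:4), paste0("a", 1:3))
    mk <- function(x) new("RwrScoreMatrix",
        rPos = matrix(x, 4, 3, dimnames = dn),
        rNeg = matrix(0, 4, 3, dimnames = dn))
    stacks <- withr::with_seed(31, lapply(
        stats::setNames(1:3, paste0("p", 1:3)),
        function(p) lapply(1:4, function(f) mk(rnorm(12)))))
    an <- interPatientAnova(stacks)
    grouping <- rep(paste0("p", 1:3), each = 4)
    for (cell in list(c(1, 1), c(2, 3), c(4, 2))) {
        vals <- unlist(lapply(stacks, function(pf)
            vapply(pf, function(f)
                scoresPos(f)[cell[1], cell[2]], numeric(1))))
        fit <- stats::anova(stats::lm(vals ~ factor(grouping)))
        expect_equal(an@fStatistic[cell[1], cell[2]], fit$`F value`[1],
                     tolerance = 1e-10)
        expect_equal(an@pValues[cell[1], cell[2]], fit$`Pr(>F)`[1],
                     tolerance = 1e-10)
    }
    ## BH is gene-wise, monotone, and never decreases a p-value
    expect_true(all(an@fdrAdjusted >= an@pValues - 1e-12))
    expect_equal(an@fdrAdjusted[2, ],
                 stats::p.adjust(an@pValues[2, ], "BH"))

    ## identical folds across patients: degenerate cells, p = 1
    same <- mk(seq_len(12))
    stacks0 <- lapply(stats::setNames(1:3, paste0("p", 1:3)),
                      function(p) list(same, same))
    an0 <- interPatientAnova(stacks0)
    expect_true(all(an0@pValues == 1))
    expect_true(all(an0@degenerate))

    ## one cell with an extreme patient effect is the only discovery
    stacks1 <- withr::with_seed(33, lapply(
        stats::setNames(1:5, paste0("p", 1:5)), function(p)
            lapply(1:4, function(f) {
                x <- matrix(rnorm(12, 0, 0.01), 4, 3, dimnames = dn)
                if (p == 1) x[2, 2] <- x[2, 2] + 10
                new("RwrScoreMatrix", rPos = x,
                    rNeg = matrix(0, 4, 3, dimnames = dn))
            })))
    an1 <- interPatientAnova(stacks1)
    sig <- an1@fdrAdjusted < 0.05
    expect_true(sig[2, 2])
    expect_identical(sum(sig), 1L)

    expect_error(interPatientAnova(stacks[1]), "2 patients")
    expect_error(interPatientAnova(lapply(stacks, `[`, 1)), "2 folds")
})

test_that("gene ranking by inter-patient variability is deterministic", {
    dn <- list(paste0("g", 1:4), paste0("a", 1:3))
    stacks <- withr::with_seed(37, lapply(
        stats::setNames(1:3, paste0("p", 1:3)), function(p)
            lapply(1:3, function(f) {
                x <- matrix(rnorm(12, 0, 0.05), 4, 3, dimnames = dn)
                x[3, ] <- x[3, ] + p      # all the signal in g3
                new("RwrScoreMatrix", rPos = x,
                    rNeg = matrix(0, 4, 3, dimnames = dn))
            })))
    expect_identical(topVariableGenes(stacks, 1), "g3")
    expect_identical(sort(topVariableGenes(stacks, 4)), paste0("g", 1:4))
    expect_warning(all5 <- topVariableGenes(stacks, 5), "exceeds")
    expect_length(all5, 4)
})
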