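#' Construct a synthetic-study specification
#'
#' All generator randomness flows from `seed`; every parameter has a
#' default sized for minutes-scale runs (see [SyntheticSpec-class]).
#'
#' @param nGenes,nCellsPerPatient,nPatients,nFolds,nModules,nAnnotations,nDrugs,nCellLines study dimensions.
#' @param moduleNoiseSd multiplicative noise sd (natural-log scale) around
#'   the shared module signal, default 0.25.
#' @param patientEffectFraction fraction of genes given a patient-specific
#'   module reassignment, default 0.05.
#' @param drugEffectMean,drugEffectSd planted drug effect magnitude
#'   (log2 scale), defaults 2 and 0.3.
#' @param denseEffectSd sd of the dense minor drug response on every gene
#'   (log2 scale, conserved across cell lines), default 0.5.
#' @param lineEffectSd sd of per-line signature noise (log2 scale),
#'   default 0.15.
#' @param sharedEffectFraction fraction of drugs whose targeted module
#'   effect is shared across cell lines, default 0.5.
#' @param offModuleRate chance an annotation links a gene outside its
#'   module, default 0.05.
#' @param seed integer master seed.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nGenes = 60L, nCellsPerPatient = 40L,
                          nPatients = 5L, nFolds = 5L, nModules = 6L,
                          nAnnotations = 12L, nDrugs = 10L, nCellLines = 5L,
                          moduleNoiseSd = 0.25, patientEffectFraction = 0.05,
                          drugEffectMean = 2, drugEffectSd = 0.3,
                          denseEffectSd = 0.5, lineEffectSd = 0.15,
                          sharedEffectFraction = 0.5,
                          offModuleRate = 0.05, seed = 1L) {
    new("SyntheticSpec", nGenes = as.integer(nGenes),
        nCellsPerPatient = as.integer(nCellsPerPatient),
        nPatients = as.integer(nPatients), nFolds = as.integer(nFolds),
        nModules = as.integer(nModules),
        nAnnotations = as.integer(nAnnotations),
        nDrugs = as.integer(nDrugs), nCellLines = as.integer(nCellLines),
        moduleNoiseSd = moduleNoiseSd,
        patientEffectFraction = patientEffectFraction,
        drugEffectMean = drugEffectMean, drugEffectSd = drugEffectSd,
        denseEffectSd = denseEffectSd, lineEffectSd = lineEffectSd,
        sharedEffectFraction = sharedEffectFraction,
        offModuleRate = offModuleRate, seed = as.integer(seed))
}

.gene_ids <- function(spec) sprintf("g%03d", seq_len(spec@nGenes))
.base_modules <- function(spec) {
    stats::setNames(rep_len(seq_len(spec@nModules), spec@nGenes),
                    .gene_ids(spec))
}

# One module-structured count matrix: shared lognormal module signal per
# cell, gene-specific constants, multiplicative lognormal noise, rounded.
# `signal` (modules x cells) can be supplied to reuse a baseline
# realisation, e.g. for drug-treated cells matched to naive controls.
.module_counts <- function(moduleOf, geneConst, nCells, noiseSd, nModules,
                           cellPrefix, signal = NULL) {
    S <- if (is.null(signal))
        matrix(exp(stats::rnorm(nModules * nCells, log(50), 0.8)),
               nModules, nCells)
    else signal[, seq_len(nCells), drop = FALSE]
    vals <- S[moduleOf, , drop = FALSE] * geneConst *
        exp(matrix(stats::rnorm(length(moduleOf) * nCells, 0, noiseSd),
                   length(moduleOf), nCells))
    m <- round(vals)
    dimnames(m) <- list(names(moduleOf),
                        paste0(cellPrefix, "_c", seq_len(nCells)))
    m
}

#' Simulate per-patient single-cell counts with planted modules
#'
#' Genes are partitioned into modules; within a module every gene tracks a
#' shared lognormal cell-level signal times a gene-specific constant times
#' multiplicative lognormal noise, so within-module pairs are
#' near-proportional (low phi_s) and between-module pairs are not. Counts
#' are rounded to integers. A `patientEffectFraction` of genes is
#' reassigned to a different module in one randomly chosen patient -- the
#' planted inter-patient signal recovered by the ANOVA analysis.
#'
#' @param spec a [SyntheticSpec-class].
#' @param seed seed override; defaults to `spec@seed`.
#' @return list with `expression` (named list patient -> genes x cells
#'   matrix), `modules` (named base module assignment) and `reassignments`
#'   (data.frame gene / patient / module describing the planted
#'   perturbations).
#' @export
simulateExpression <- function(spec, seed = spec@seed) {
    stopifnot(is(spec, "SyntheticSpec"))
    base <- .base_modules(spec)
    .with_seed(seed, {
        geneConst <- exp(stats::rnorm(spec@nGenes, 0, 0.5))
        nAff <- round(spec@patientEffectFraction * spec@nGenes)
        reass <- data.frame(gene = character(), patient = character(),
                            module = integer())
        if (nAff > 0 && spec@nModules > 1L) {
            aff <- sample.int(spec@nGenes, nAff)
            reass <- data.frame(
                gene = .gene_ids(spec)[aff],
                patient = paste0("patient", sample.int(spec@nPatients, nAff,
                                                       replace = TRUE)),
                module = vapply(aff, function(i)
                    sample(setdiff(seq_len(spec@nModules), base[i]), 1L),
                    integer(1)))
        }
        expr <- list()
        for (p in seq_len(spec@nPatients)) {
            pid <- paste0("patient", p)
            mod <- base
            hit <- reass$patient == pid
            mod[reass$gene[hit]] <- reass$module[hit]
            expr[[pid]] <- .module_counts(mod, geneConst,
                                          spec@nCellsPerPatient,
                                          spec@moduleNoiseSd, spec@nModules,
                                          paste0("p", p))
        }
        list(expression = expr, modules = base, reassignments = reass)
    })
}

#' Simulate a module-aligned annotation graph
#'
#' Each annotation is attached to all genes of one module (annotations
#' cycle through the modules) plus a small random fraction of off-module
#' genes, giving a binary graph in which every gene and every annotation
#' has at least one link.
#'
#' @inheritParams simulateExpression
#' @return list with `graph` (an annotation [BipartiteGraph-class]) and
#'   `moduleOf` (integer vector: the module each annotation marks).
#' @export
simulateAnnotations <- function(spec, seed = spec@seed) {
    stopifnot(is(spec, "SyntheticSpec"))
    if (spec@nAnnotations < spec@nModules)
        stop("need at least one annotation per module so no gene is isolated")
    base <- .base_modules(spec)
    annIds <- sprintf("a%03d", seq_len(spec@nAnnotations))
    moduleOf <- stats::setNames(
        rep_len(seq_len(spec@nModules), spec@nAnnotations), annIds)
    w <- .with_seed(.child_seed(seed, 17L), {
        w <- matrix(0, spec@nGenes, spec@nAnnotations,
                    dimnames = list(names(base), annIds))
        for (a in seq_along(annIds)) {
            members <- base == moduleOf[a]
            off <- stats::runif(spec@nGenes) < spec@offModuleRate
            w[members | off, a] <- 1
        }
        w
    })
    list(graph = new("BipartiteGraph", weights = w,
                     targetKind = "annotation"),
         moduleOf = moduleOf)
}

#' Simulate drug-treated and drug-naive expression per cell line
#'
#' Every drug carries a gene-level log2 response signature with two
#' parts. A dense minor response ~ Normal(0, `denseEffectSd`) over all
#' genes is conserved across cell lines (the compound-specific
#' transcriptional baseline; expression signatures perturb everything a
#' little, not just the targeted pathway). On top of it the drug up- or
#' down-regulates the genes of one module with a strong signed effect of
#' magnitude ~ Normal(`drugEffectMean`, `drugEffectSd`): for a
#' `sharedEffectFraction` of drugs this targeted effect is identical in
#' every cell line, for the rest each line draws its own sign and
#' magnitude (the cell-context-dependent part of the response). Each line
#' additionally adds Normal(0, `lineEffectSd`) line-level noise to the
#' whole signature.
#'
#' Treated cells reuse the naive cells' baseline module signal (matched
#' controls), so the median log2 fold change isolates the planted
#' signature. Naive cells follow the same module-structured count model as
#' [simulateExpression()], so each line's naive matrix yields a
#' module-aware co-expression network.
#'
#' @inheritParams simulateExpression
#' @param nTreatedCells treated cells per drug; defaults to
#'   `spec@nCellsPerPatient` so treated and naive medians are matched.
#' @return list with `lines` (named list: cell line ->
#'   list(naive, treated)), `effectMatrices` (named list: cell line ->
#'   genes x drugs matrix of planted log2 effects) and `effects`
#'   (data.frame line / drug / module / effect / shared with the realised
#'   module-level effect per line).
#' @export
simulateDrugResponses <- function(spec, seed = spec@seed,
                                  nTreatedCells = spec@nCellsPerPatient) {
    stopifnot(is(spec, "SyntheticSpec"))
    base <- .base_modules(spec)
    drugIds <- sprintf("d%03d", seq_len(spec@nDrugs))
    drugModule <- rep_len(seq_len(spec@nModules), spec@nDrugs)
    if (nTreatedCells > spec@nCellsPerPatient)
        stop("nTreatedCells cannot exceed nCellsPerPatient (treated cells ",
             "are matched to naive baseline cells)")
    nSharedDrugs <- round(spec@sharedEffectFraction * spec@nDrugs)
    .with_seed(.child_seed(seed, 29L), {
        dense <- matrix(stats::rnorm(spec@nGenes * spec@nDrugs, 0,
                                     spec@denseEffectSd),
                        spec@nGenes, spec@nDrugs)
        sharedEff <- sample(c(-1, 1), spec@nDrugs, replace = TRUE) *
            abs(stats::rnorm(spec@nDrugs, spec@drugEffectMean,
                             spec@drugEffectSd))
        lines <- list()
        effectMatrices <- list()
        effects <- NULL
        for (l in seq_len(spec@nCellLines)) {
            lid <- paste0("line", l)
            geneConst <- exp(stats::rnorm(spec@nGenes, 0, 0.5))
            baseSignal <- matrix(
                exp(stats::rnorm(spec@nModules * spec@nCellsPerPatient,
                                 log(50), 0.8)),
                spec@nModules, spec@nCellsPerPatient)
            naive <- .module_counts(base, geneConst, spec@nCellsPerPatient,
                                    spec@moduleNoiseSd, spec@nModules,
                                    paste0(lid, "_naive"),
                                    signal = baseSignal)
            E <- dense + matrix(stats::rnorm(spec@nGenes * spec@nDrugs, 0,
                                             spec@lineEffectSd),
                                spec@nGenes, spec@nDrugs)
            dimnames(E) <- list(names(base), drugIds)
            treated <- list()
            for (d in seq_len(spec@nDrugs)) {
                shared <- d <= nSharedDrugs
                eff <- if (shared) sharedEff[d] else
                    sample(c(-1, 1), 1L) *
                        abs(stats::rnorm(1L, spec@drugEffectMean,
                                         spec@drugEffectSd))
                inMod <- base == drugModule[d]
                E[inMod, d] <- E[inMod, d] + eff
                ## treated cells share the naive baseline signal (matched
                ## controls): the log-fold change isolates the drug effect
                tm <- .module_counts(base, geneConst * 2^E[, d],
                                     nTreatedCells, spec@moduleNoiseSd,
                                     spec@nModules,
                                     paste0(lid, "_", drugIds[d]),
                                     signal = baseSignal)
                treated[[drugIds[d]]] <- tm
                effects <- rbind(effects, data.frame(
                    line = lid, drug = drugIds[d], module = drugModule[d],
                    effect = eff, shared = shared))
            }
            lines[[lid]] <- list(naive = naive, treated = treated)
            effectMatrices[[lid]] <- E
        }
        list(lines = lines, effectMatrices = effectMatrices,
             effects = effects)
    })
}

#' Split cells into random near-equal folds
#'
#' Random partition of the columns of an expression matrix into `nFolds`
#' parts whose sizes differ by at most one; the union of the folds is the
#' input and the partition is deterministic given the seed.
#'
#' @param expr genes x cells matrix.
#' @param nFolds number of folds.
#' @param seed integer seed.
#' @return list of `nFolds` column-subset matrices.
#' @export
splitFolds <- function(expr, nFolds, seed) {
    m <- .expr_matrix(expr)
    nFolds <- as.integer(nFolds)
    if (nFolds < 1L || nFolds > ncol(m))
        stop("nFolds must be between 1 and the number of cells")
    .with_seed(seed, {
        perm <- sample.int(ncol(m))
        sizes <- rep(ncol(m) %/% nFolds, nFolds) +
            c(rep(1L, ncol(m) %% nFolds),
              rep(0L, nFolds - ncol(m) %% nFolds))
        ends <- cumsum(sizes)
        starts <- c(1L, utils::head(ends, -1L) + 1L)
        lapply(seq_len(nFolds), function(i)
            m[, sort(perm[starts[i]:ends[i]]), drop = FALSE])
    })
}
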