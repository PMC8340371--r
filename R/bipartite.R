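#' Binary gene-annotation bipartite graph
#'
#' An edge of weight 1 exists wherever a gene is associated with an
#' annotation (Gene Ontology terms flattened to a plain bipartite graph;
#' no term-term semantics). Duplicate pairs collapse silently.
#'
#' @param pairs two-column data.frame (gene, annotation) or a list/matrix
#'   coercible to one.
#' @param geneUniverse,targetUniverse optional identifier vectors fixing
#'   the row/column universes; defaults to the distinct values observed.
#' @return a [BipartiteGraph-class] with `targetKind = "annotation"`.
#' @examples
#' g <- annotationGraph(data.frame(gene = c("g1", "g2", "g2"),
#'                                 annotation = c("a1", "a1", "a2")))
#' weightMatrix(g)
#' @export
annotationGraph <- function(pairs, geneUniverse = NULL,
                            targetUniverse = NULL) {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    if (nrow(pairs) == 0L) stop("pair list is empty")
    if (ncol(pairs) < 2L) stop("pairs must have (gene, annotation) columns")
    genes <- as.character(pairs[[1L]])
    anns <- as.character(pairs[[2L]])
    if (is.null(geneUniverse)) geneUniverse <- unique(genes)
    if (is.null(targetUniverse)) targetUniverse <- unique(anns)
    bad <- !(genes %in% geneUniverse) | !(anns %in% targetUniverse)
    if (any(bad)) {
        genes <- genes[!bad]; anns <- anns[!bad]
        if (length(genes) == 0L) stop("no pair falls inside the universes")
    }
    w <- matrix(0, length(geneUniverse), length(targetUniverse),
                dimnames = list(geneUniverse, targetUniverse))
    w[cbind(genes, anns)] <- 1
    new("BipartiteGraph", weights = w, targetKind = "annotation")
}

#' Signed gene-drug response graph from treated vs naive expression
#'
#' For every drug d and gene g the edge weight is the log2 fold change
#' between median expression in the drug-treated cells and median
#' expression in drug-naive cells,
#' \eqn{w_{gd} = \log_2((med_g(treated_d) + \epsilon) /
#' (med_g(naive) + \epsilon))}, a pseudocount \eqn{\epsilon} guarding zero
#' medians. The result is a fully connected weighted bipartite graph;
#' positive weights mean the drug up-regulates the gene.
#'
#' @param treated named list mapping drug id to a genes x cells matrix of
#'   treated expression.
#' @param naive genes x cells matrix of drug-naive expression over the same
#'   gene universe.
#' @param epsilon pseudocount added to both medians, default 1.
#' @return a [BipartiteGraph-class] with `targetKind = "drug"`.
#' @export
drugResponseGraph <- function(treated, naive, epsilon = 1) {
    if (!is.list(treated) || is.null(names(treated)) ||
        length(treated) == 0L)
        stop("treated must be a nonempty named list (drug -> matrix)")
    naive <- .expr_matrix(naive)
    genes <- rownames(naive)
    w <- matrix(NA_real_, length(genes), length(treated),
                dimnames = list(genes, names(treated)))
    med_naive <- apply(naive, 1L, stats::median)
    for (d in names(treated)) {
        td <- .expr_matrix(treated[[d]])
        if (ncol(td) == 0L) stop("treated matrix for drug '", d, "' is empty")
        if (!setequal(rownames(td), genes)) {
            off <- union(setdiff(rownames(td), genes),
                         setdiff(genes, rownames(td)))
            stop("gene universe mismatch for drug '", d, "': ",
                 paste(utils::head(off, 10L), collapse = ", "))
        }
        med_t <- apply(td[genes, , drop = FALSE], 1L, stats::median)
        w[, d] <- log2((med_t + epsilon) / (med_naive + epsilon))
    }
    new("BipartiteGraph", weights = w, targetKind = "drug")
}

#' Elementwise-average composite of bipartite graphs
#'
#' Averages the edge weights of several gene-target graphs (e.g. the drug
#' responses of several cell lines) into one general-knowledge graph.
#' Graphs are aligned on the intersection of their gene and target
#' universes; dropped identifiers are reported in a message.
#'
#' @param graphs list of at least two [BipartiteGraph-class] objects of the
#'   same `targetKind`.
#' @return a [BipartiteGraph-class] of the averaged weights. A composite of
#'   annotation graphs is returned with `targetKind = "drug"`-style real
#'   weights only if inputs differ; identical binary inputs stay binary.
#' @export
compositeGraph <- function(graphs) {
    if (!is.list(graphs) || length(graphs) < 2L)
        stop("need at least two graphs")
    stopifnot(all(vapply(graphs, is, logical(1), "BipartiteGraph")))
    kinds <- unique(vapply(graphs, targetKind, character(1)))
    if (length(kinds) != 1L) stop("graphs mix annotation and drug kinds")
    genes <- Reduce(intersect, lapply(graphs, geneIds))
    targets <- Reduce(intersect, lapply(graphs, targetIds))
    if (length(genes) == 0L || length(targets) == 0L)
        stop("empty intersection of gene or target universes")
    dropped <- sum(vapply(graphs, function(g)
        length(setdiff(geneIds(g), genes)), integer(1)))
    if (dropped > 0)
        message(dropped, " gene id(s) outside the common universe dropped")
    acc <- matrix(0, length(genes), length(targets),
                  dimnames = list(genes, targets))
    for (g in graphs)
        acc <- acc + weightMatrix(g)[genes, targets, drop = FALSE]
    w <- acc / length(graphs)
    kind <- if (kinds == "annotation" && all(w %in% c(0, 1)))
        "annotation" else "drug"
    new("BipartiteGraph", weights = w, targetKind = kind)
}

#' Join a co-expression network and a bipartite graph
#'
#' Assembles the heterogeneous graph the walk runs on: block adjacency
#' `[[phi_i, W], [t(W), 0]]` over genes followed by targets, with a zero
#' diagonal (self-similarity is dropped; no self-loops feed the
#' transitions). Both inputs are restricted to their common gene universe.
#'
#' @param net a [CoexpressionNetwork-class].
#' @param bip a [BipartiteGraph-class] whose genes overlap the network's.
#' @return a [HeterogeneousGraph-class].
#' @export
joinGraphs <- function(net, bip) {
    stopifnot(is(net, "CoexpressionNetwork"), is(bip, "BipartiteGraph"))
    genes <- intersect(geneIds(net), geneIds(bip))
    if (length(genes) == 0L) stop("empty gene intersection")
    ndrop <- length(setdiff(geneIds(net), genes)) +
        length(setdiff(geneIds(bip), genes))
    if (ndrop > 0)
        message(ndrop, " gene id(s) outside the common universe dropped")
    targets <- targetIds(bip)
    if (any(targets %in% genes))
        stop("target identifiers collide with gene identifiers")
    gg <- phiI(net)[genes, genes, drop = FALSE]
    diag(gg) <- 0
    W <- weightMatrix(bip)[genes, targets, drop = FALSE]
    if (all(W == 0))
        warning("bipartite block is all-zero: every target is isolated")
    n <- length(genes) + length(targets)
    adj <- matrix(0, n, n,
                  dimnames = list(c(genes, targets), c(genes, targets)))
    adj[seq_along(genes), seq_along(genes)] <- gg
    adj[seq_along(genes), length(genes) + seq_along(targets)] <- W
    adj[length(genes) + seq_along(targets), seq_along(genes)] <- t(W)
    iso <- colnames(W)[colSums(W != 0) == 0]
    if (length(iso) && !all(W == 0))
        warning("isolated target node(s): ", paste(iso, collapse = ", "))
    new("HeterogeneousGraph", adjacency = adj,
        nodeKind = c(rep("gene", length(genes)),
                     rep("target", length(targets))),
        targetKind = targetKind(bip))
}
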