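# Matrix <-> TSV helpers. Values are written with 17 significant digits so
# a write/read round trip reproduces doubles exactly.

.write_matrix_tsv <- function(m, path, rowLabel = "id") {
    chr <- formatC(m, digits = 17, format = "g")
    out <- cbind(rownames(m), chr)
    colnames(out) <- c(rowLabel, colnames(m))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

.read_matrix_tsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    nf <- utils::count.fields(path, sep = "\t", quote = "")
    if (length(nf) < 2L) stop("malformed matrix file ", path,
                              ": fewer than 2 lines")
    bad <- which(nf != nf[1L])
    if (length(bad))
        stop("malformed matrix file ", path, ": line ", bad[1L] + 0L,
             " has ", nf[bad[1L]], " fields, expected ", nf[1L])
    df <- utils::read.delim(path, check.names = FALSE, row.names = 1L,
                            quote = "")
    as.matrix(df)
}

#' Read and write expression matrices
#'
#' `readExpression()` reads a genes x samples table (first column gene id,
#' header row sample ids; tab- or comma-separated by file extension) and
#' `writeExpression()` writes one. `readExpressionMM()` reads a
#' MatrixMarket file with two sidecar id files (one id per line);
#' `writeExpressionMM()` writes that triple.
#'
#' @param path file path (`.tsv`/`.txt` tab-separated, `.csv`
#'   comma-separated).
#' @param expr genes x samples numeric matrix.
#' @param mtx,geneFile,sampleFile MatrixMarket file and its gene/sample id
#'   sidecars.
#' @return a numeric matrix with gene/sample dimnames (readers) or the
#'   path, invisibly (writers).
#' @name expression-io
NULL

#' @rdname expression-io
#' @export
readExpression <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    nf <- utils::count.fields(path, sep = sep, quote = "\"")
    bad <- which(nf != nf[1L])
    if (length(bad))
        stop("malformed expression file ", path, ": line ", bad[1L],
             " has ", nf[bad[1L]], " fields, expected ", nf[1L])
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, row.names = 1L)
    .expr_matrix(as.matrix(df))
}

#' @rdname expression-io
#' @export
writeExpression <- function(expr, path) {
    m <- .expr_matrix(expr)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    chr <- formatC(m, digits = 17, format = "g")
    out <- cbind(gene = rownames(m), chr)
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname expression-io
#' @export
readExpressionMM <- function(mtx, geneFile, sampleFile) {
    m <- as.matrix(Matrix::readMM(mtx))
    genes <- readLines(geneFile)
    samples <- readLines(sampleFile)
    if (nrow(m) != length(genes) || ncol(m) != length(samples))
        stop("sidecar id counts (", length(genes), " x ", length(samples),
             ") do not match matrix dimensions (", nrow(m), " x ", ncol(m),
             ")")
    dimnames(m) <- list(genes, samples)
    .expr_matrix(m)
}

#' @rdname expression-io
#' @export
writeExpressionMM <- function(expr, mtx, geneFile, sampleFile) {
    m <- .expr_matrix(expr)
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), mtx)
    writeLines(rownames(m), geneFile)
    writeLines(colnames(m), sampleFile)
    invisible(mtx)
}

#' Read and write co-expression networks and bipartite graphs
#'
#' Networks are square TSVs with gene ids on both axes; bipartite graphs
#' are genes x targets TSVs. Values round-trip exactly.
#'
#' @param net a [CoexpressionNetwork-class].
#' @param bip a [BipartiteGraph-class].
#' @param path file path.
#' @param targetKind `"annotation"` or `"drug"` for [readBipartite()].
#' @name graph-io
NULL

#' @rdname graph-io
#' @export
writeNetwork <- function(net, path) {
    stopifnot(is(net, "CoexpressionNetwork"))
    .write_matrix_tsv(phiI(net), path, "gene")
}

#' @rdname graph-io
#' @export
readNetwork <- function(path) {
    m <- .read_matrix_tsv(path)
    new("CoexpressionNetwork", phi = m, provenance = list(source = path))
}

#' @rdname graph-io
#' @export
writeBipartite <- function(bip, path) {
    stopifnot(is(bip, "BipartiteGraph"))
    .write_matrix_tsv(weightMatrix(bip), path, "gene")
}

#' @rdname graph-io
#' @export
readBipartite <- function(path, targetKind = c("drug", "annotation")) {
    targetKind <- match.arg(targetKind)
    m <- .read_matrix_tsv(path)
    new("BipartiteGraph", weights = m, targetKind = targetKind)
}

#' Read gene-annotation associations
#'
#' `readAnnotationPairs()` reads a two-column TSV (gene, annotation);
#' `readGMT()` reads GMT gene-set files (set name, description, members);
#' duplicate members collapse to one link. Both return a binary
#' [BipartiteGraph-class].
#'
#' @param path file path.
#' @return an annotation [BipartiteGraph-class].
#' @name annotation-io
NULL

#' @rdname annotation-io
#' @export
readAnnotationPairs <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    nf <- utils::count.fields(path, sep = "\t", quote = "")
    bad <- which(nf < 2L)
    if (length(bad))
        stop("malformed pair file ", path, ": line ", bad[1L],
             " has fewer than 2 fields")
    df <- utils::read.delim(path, header = FALSE, quote = "",
                            colClasses = "character")
    annotationGraph(df[, 1:2])
}

#' @rdname annotation-io
#' @export
readGMT <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    pairs <- NULL
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            stop("malformed GMT file ", path, ": line ", i,
                 " has fewer than 3 fields")
        members <- unique(f[-(1:2)])
        pairs <- rbind(pairs, data.frame(gene = members, annotation = f[1L]))
    }
    annotationGraph(pairs)
}

#' Read and write score matrices in long format
#'
#' Long-format TSV with columns gene, target, channel
#' (`positive`/`negative`), score -- the exchange format for downstream
#' statistics. Values round-trip exactly.
#'
#' @param scores an [RwrScoreMatrix-class].
#' @param path file path.
#' @name score-io
NULL

#' @rdname score-io
#' @export
writeScores <- function(scores, path) {
    stopifnot(is(scores, "RwrScoreMatrix"))
    long <- function(m, ch) data.frame(
        gene = rownames(m)[row(m)], target = colnames(m)[col(m)],
        channel = ch, score = formatC(as.vector(m), digits = 17,
                                      format = "g"))
    df <- rbind(long(scoresPos(scores), "positive"),
                long(scoresNeg(scores), "negative"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname score-io
#' @export
readScores <- function(path) {
    df <- utils::read.delim(path, quote = "",
                            colClasses = c("character", "character",
                                           "character", "numeric"))
    if (!identical(names(df), c("gene", "target", "channel", "score")))
        stop("malformed score file ", path,
             ": expected columns gene, target, channel, score")
    genes <- unique(df$gene); targets <- unique(df$target)
    build <- function(ch) {
        sub <- df[df$channel == ch, ]
        m <- matrix(NA_real_, length(genes), length(targets),
                    dimnames = list(genes, targets))
        m[cbind(sub$gene, sub$target)] <- sub$score
        m
    }
    rp <- build("positive"); rn <- build("negative")
    failed <- genes[apply(is.na(rp), 1L, all) & apply(is.na(rn), 1L, all)]
    new("RwrScoreMatrix", rPos = rp, rNeg = rn, failed = failed)
}

#' Read and write provenance JSON
#'
#' Records run parameters (seeds, thresholds, gene counts) next to result
#' files so every protocol run is reproducible.
#'
#' @param x named list of parameters.
#' @param path file path.
#' @name provenance-io
NULL

#' @rdname provenance-io
#' @export
writeProvenance <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname provenance-io
#' @export
readProvenance <- function(path) {
    jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Rename genes through a strictly one-to-one id mapping
#'
#' Keeps only genes whose source id maps to exactly one target id and
#' whose target id is reached from exactly one source (e.g. an Ensembl to
#' HGNC table), renames the surviving genes, and reports how many were
#' dropped.
#'
#' @param expr genes x samples matrix keyed by source ids.
#' @param mapping two-column data.frame (source id, target id).
#' @return the renamed, row-subset expression matrix.
#' @export
mapGeneIds <- function(expr, mapping) {
    m <- .expr_matrix(expr)
    mapping <- as.data.frame(mapping, stringsAsFactors = FALSE)
    if (nrow(mapping) == 0L) stop("mapping is empty")
    src <- as.character(mapping[[1L]]); dst <- as.character(mapping[[2L]])
    keepPair <- !(src %in% src[duplicated(src)]) &
        !(dst %in% dst[duplicated(dst)])
    src <- src[keepPair]; dst <- dst[keepPair]
    idx <- match(rownames(m), src)
    keep <- !is.na(idx)
    if (!any(keep))
        stop("no gene survives the 1-to-1 mapping")
    dropped <- sum(!keep)
    if (dropped > 0)
        message(dropped, " gene(s) without a 1-to-1 mapping dropped")
    out <- m[keep, , drop = FALSE]
    rownames(out) <- dst[idx[keep]]
    out
}
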