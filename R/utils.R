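# Shared internal helpers.

# Coerce an expression input (numeric matrix with dimnames, data.frame, or
# SummarizedExperiment) to a plain genes x samples numeric matrix.
.expr_matrix <- function(expr) {
    if (is(expr, "SummarizedExperiment")) {
        if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
            stop("SummarizedExperiment input requires the ",
                 "SummarizedExperiment package")
        expr <- SummarizedExperiment::assay(expr)
    }
    if (is.data.frame(expr)) expr <- as.matrix(expr)
    if (!is.matrix(expr) || !is.numeric(expr))
        stop("expression input must be a numeric matrix (genes x samples)")
    if (is.null(rownames(expr)))
        rownames(expr) <- paste0("g", seq_len(nrow(expr)))
    if (is.null(colnames(expr)))
        colnames(expr) <- paste0("s", seq_len(ncol(expr)))
    if (anyDuplicated(rownames(expr)) || anyDuplicated(colnames(expr)))
        stop("gene and sample identifiers must be unique")
    if (any(expr < 0)) stop("expression values must be nonnegative")
    expr
}

# Derive a reproducible child seed from a master seed and an index, kept
# within 32-bit integer range.
.child_seed <- function(seed, index) {
    as.integer((as.double(seed) * 48271 + as.double(index) * 9973) %%
               2147483647)
}

# Evaluate expr with a locally-set RNG seed, restoring global RNG state.
.with_seed <- function(seed, expr) {
    withr::with_seed(as.integer(seed), expr)
}
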