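# Internal helpers shared across modules.

# Run code under a fixed seed with a pinned generator, restoring RNG state.
# Pinning the kind makes seeded structures reproducible across sessions.
.withSeed <- function(seed, code) {
    withr::with_seed(as.integer(seed), code,
                     .rng_kind = "Mersenne-Twister",
                     .rng_normal_kind = "Inversion",
                     .rng_sample_kind = "Rejection")
}

.assertCount <- function(x, name) {
    if (length(x) != 1L || is.na(x) || x < 1)
        stop(name, " must be a single positive integer", call. = FALSE)
    as.integer(x)
}

# Coerce a single expression vector, keeping names as gene ids when present.
.asExpressionVector <- function(x) {
    if (is.matrix(x) && any(dim(x) == 1L)) x <- drop(x)
    if (!is.numeric(x) || length(x) < 1L)
        stop("expression vector must be numeric with at least one gene",
             call. = FALSE)
    if (any(!is.finite(x)))
        stop("expression vector contains non-finite values", call. = FALSE)
    x
}

# Extract a genes x cells numeric matrix from matrix-like input
# (base matrix, Matrix, or SummarizedExperiment/SingleCellExperiment).
.asExpressionMatrix <- function(x) {
    if (methods::is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x, 1L)
    if (methods::is(x, "Matrix")) x <- as.matrix(x)
    if (!is.matrix(x)) x <- as.matrix(x)
    storage.mode(x) <- "double"
    if (nrow(x) < 1L || ncol(x) < 1L)
        stop("expression matrix must have at least one gene and one cell",
             call. = FALSE)
    x
}

# Labels from an argument or the colData 'group' column of an SCE.
.resolveLabels <- function(x, labels) {
    if (!is.null(labels)) return(as.character(labels))
    if (methods::is(x, "SummarizedExperiment")) {
        cd <- SummarizedExperiment::colData(x)
        if ("group" %in% colnames(cd)) return(as.character(cd$group))
    }
    NULL
}
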