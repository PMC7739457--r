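#' Centralize expression values
#'
#' Subtracts each cell's mean expression over all genes from that cell's
#' expression values, so that a cell's centralized profile has mean zero.
#' This is the only preprocessing the hash encoders assume; it works on any
#' expression unit (counts, UMIs, RPKM, TPM) as long as queries and
#' references use the same unit.
#'
#' @param x A numeric vector (one cell) or a genes x cells matrix.
#' @return The centralized vector or matrix (cells centralized columnwise).
#' @examples
#' centralizeExpression(c(1, 2, 3))
#' @export
centralizeExpression <- function(x) {
    if (is.matrix(x) || methods::is(x, "Matrix")) {
        x <- .asExpressionMatrix(x)
        return(sweep(x, 2L, colMeans(x), "-"))
    }
    x <- .asExpressionVector(x)
    x - mean(x)
}

#' Generate a SimHash random projection basis
#'
#' Draws `embeddingSize` projection vectors of length `d` with entries
#' i.i.d. standard normal. The basis is regenerated bit-exactly from
#' `(d, embeddingSize, seed)`.
#'
#' @param d Input dimensionality (number of genes).
#' @param embeddingSize Number of projections, i.e. long-hash bits.
#' @param seed Integer seed.
#' @return A numeric `embeddingSize` x `d` matrix; one projection per row.
#' @export
makeSimHashBasis <- function(d, embeddingSize, seed) {
    d <- .assertCount(d, "d")
    embeddingSize <- .assertCount(embeddingSize, "embeddingSize")
    .withSeed(seed, matrix(stats::rnorm(embeddingSize * d),
                           nrow = embeddingSize, ncol = d))
}

#' SimHash encoding
#'
#' Each bit is the sign indicator of the dot product between the input and
#' one random projection: 1 when `x . r_p >= 0`, else 0, concatenated in
#' projection order. Invariant under positive rescaling of the input.
#'
#' @param x A numeric vector of length `d` (or a genes x cells matrix).
#' @param basis A projection matrix from [makeSimHashBasis()].
#' @return Integer 0/1 vector of `nrow(basis)` bits (for a matrix input, a
#'   cells x bits matrix).
#' @export
simhashEncode <- function(x, basis) {
    if (!is.matrix(basis))
        stop("basis must be a projection matrix", call. = FALSE)
    if (is.matrix(x) || methods::is(x, "Matrix")) {
        x <- .asExpressionMatrix(x)
        if (nrow(x) != ncol(basis))
            stop("dimension mismatch: basis expects ", ncol(basis),
                 " genes, got ", nrow(x), call. = FALSE)
        bits <- t(basis %*% x >= 0)
        storage.mode(bits) <- "integer"
        return(bits)
    }
    x <- .asExpressionVector(x)
    if (length(x) != ncol(basis))
        stop("dimension mismatch: basis expects ", ncol(basis),
             " genes, got ", length(x), call. = FALSE)
    as.integer(drop(basis %*% x) >= 0)
}

#' Generate a gene sampling plan
#'
#' For each of the `embeddingSize` activations, samples
#' `floor(alpha * d)` distinct gene indices uniformly without replacement,
#' independently per activation. Regenerable from
#' `(d, embeddingSize, alpha, seed)`.
#'
#' @param d Number of genes.
#' @param embeddingSize Number of activations (`m * k`).
#' @param alpha Sampling rate in (0, 1].
#' @param seed Integer seed.
#' @return A list of `embeddingSize` integer index vectors (1-based), with
#'   attributes `d`, `alpha` and `seed`.
#' @export
makeSamplingPlan <- function(d, embeddingSize, alpha, seed) {
    d <- .assertCount(d, "d")
    embeddingSize <- .assertCount(embeddingSize, "embeddingSize")
    s <- floor(alpha * d)
    if (s < 1)
        stop("floor(alpha * d) must be at least 1 (alpha = ", alpha,
             ", d = ", d, ")", call. = FALSE)
    plan <- .withSeed(seed, lapply(seq_len(embeddingSize),
                                   function(i) sample.int(d, s)))
    attr(plan, "d") <- d
    attr(plan, "alpha") <- alpha
    attr(plan, "seed") <- as.integer(seed)
    plan
}

# Sampling plan as a sparse 0/1 matrix for fast activation of many cells.
.planMatrix <- function(plan) {
    s <- lengths(plan)
    Matrix::sparseMatrix(
        i = rep.int(seq_along(plan), s),
        j = unlist(plan, use.names = FALSE),
        x = 1,
        dims = c(length(plan), attr(plan, "d")))
}

#' Compute fly-scheme activations
#'
#' Activation `i` is the sum of the input over the i-th sampled gene set.
#'
#' @param x Numeric vector of length `d` (or genes x cells matrix).
#' @param plan A sampling plan from [makeSamplingPlan()].
#' @return Numeric activation vector of length `length(plan)` (or an
#'   activations x cells matrix).
#' @export
computeActivations <- function(x, plan) {
    maxIdx <- max(vapply(plan, max, 0L))
    if (is.matrix(x) || methods::is(x, "Matrix")) {
        x <- .asExpressionMatrix(x)
        if (maxIdx > nrow(x))
            stop("sampling plan indexes gene ", maxIdx, " but matrix has ",
                 nrow(x), " genes", call. = FALSE)
        return(as.matrix(.planMatrix(plan) %*% x))
    }
    x <- .asExpressionVector(x)
    if (maxIdx > length(x))
        stop("sampling plan indexes gene ", maxIdx, " but vector has ",
             length(x), " genes", call. = FALSE)
    vapply(plan, function(ix) sum(x[ix]), numeric(1))
}

#' Partition activations into shuffle groups
#'
#' A seeded random permutation of the `m * k` activation indices cut into
#' `m` consecutive blocks of `k`: a disjoint partition, so the `m`
#' winner-take-all blocks concatenate to exactly `m * k` bits.
#'
#' @param m Number of groups.
#' @param k Group size.
#' @param seed Integer seed.
#' @return A list of `m` disjoint integer vectors of length `k` covering
#'   `1..m*k`, with attributes `m`, `k`, `seed`.
#' @export
partitionGroups <- function(m, k, seed) {
    m <- .assertCount(m, "m")
    k <- .assertCount(k, "k")
    perm <- .withSeed(seed, sample.int(m * k))
    groups <- unname(split(perm, rep(seq_len(m), each = k)))
    attr(groups, "m") <- m
    attr(groups, "k") <- k
    attr(groups, "seed") <- as.integer(seed)
    groups
}

.checkActivationLength <- function(a, groups) {
    mk <- sum(lengths(groups))
    if (length(a) != mk)
        stop("activation vector has length ", length(a),
             " but the partition covers ", mk, " activations", call. = FALSE)
}

#' FlyHash winner-take-all encoding
#'
#' Each shuffle group of `k` activations becomes a one-hot block with a
#' single 1 at the within-group maximum (ties broken by the lowest
#' within-group position); blocks are concatenated in group order, so the
#' long hash has Hamming weight exactly `m`.
#'
#' @param a Activation vector of length `m * k` (or activations x cells
#'   matrix).
#' @param groups A partition from [partitionGroups()].
#' @return Integer 0/1 vector of `m * k` bits (or cells x bits matrix).
#' @export
flyhashEncode <- function(a, groups) {
    k <- attr(groups, "k")
    if (is.matrix(a)) {
        .checkActivationLength(a[, 1L], groups)
        n <- ncol(a)
        bits <- matrix(0L, nrow = n, ncol = length(groups) * k)
        for (j in seq_along(groups)) {
            sub <- a[groups[[j]], , drop = FALSE]           # k x n
            win <- max.col(t(sub), ties.method = "first")   # per cell
            bits[cbind(seq_len(n), (j - 1L) * k + win)] <- 1L
        }
        return(bits)
    }
    .checkActivationLength(a, groups)
    bits <- integer(length(a))
    for (j in seq_along(groups)) {
        vals <- a[groups[[j]]]
        bits[(j - 1L) * k + which.max(vals)] <- 1L
    }
    bits
}

#' DenseFly sign encoding
#'
#' Within each shuffle group, strictly positive activations become 1 and all
#' others (including exact zeros) become 0; blocks concatenate in group
#' order. The code is denser than FlyHash's one-hot blocks.
#'
#' @inheritParams flyhashEncode
#' @return Integer 0/1 vector of `m * k` bits (or cells x bits matrix).
#' @export
denseflyEncode <- function(a, groups) {
    ord <- unlist(groups, use.names = FALSE)
    if (is.matrix(a)) {
        .checkActivationLength(a[, 1L], groups)
        bits <- t(a[ord, , drop = FALSE] > 0)
        storage.mode(bits) <- "integer"
        return(bits)
    }
    .checkActivationLength(a, groups)
    as.integer(a[ord] > 0)
}

#' Pseudo-hash (short hash)
#'
#' Bit `j` is 1 when the sum of all `k` activations in shuffle group `j` is
#' strictly positive, giving an m-bit coarse summary used for multi-probe
#' candidate retrieval.
#'
#' @inheritParams flyhashEncode
#' @return Integer 0/1 vector of `m` bits (or cells x m matrix).
#' @export
pseudoHash <- function(a, groups) {
    ord <- unlist(groups, use.names = FALSE)
    g <- rep(seq_along(groups), lengths(groups))
    if (is.matrix(a)) {
        .checkActivationLength(a[, 1L], groups)
        sums <- rowsum(a[ord, , drop = FALSE], g)  # m x n, ordered by group
        bits <- t(sums > 0)
        storage.mode(bits) <- "integer"
        colnames(bits) <- NULL
        return(bits)
    }
    .checkActivationLength(a, groups)
    sums <- vapply(groups, function(ix) sum(a[ix]), numeric(1))
    as.integer(sums > 0)
}

#' Build the seeded random structures for a configuration
#'
#' SimHash needs a Gaussian projection basis; the fly schemes need a gene
#' sampling plan (seeded with `seed`) and a shuffle-group partition (seeded
#' with `seed + 1`). Rebuilding with the same `(config, d)` reproduces the
#' structures bit-exactly, which is what makes serialized indexes
#' self-contained.
#'
#' @param config A [HashConfig-class].
#' @param d Number of genes.
#' @return A list with element `basis` (simhash) or elements `plan` and
#'   `partition` (fly schemes).
#' @export
hashStructures <- function(config, d) {
    stopifnot(methods::is(config, "HashConfig"))
    d <- .assertCount(d, "d")
    if (config@method == "simhash") {
        list(basis = makeSimHashBasis(d, embeddingSize(config), config@seed))
    } else {
        list(plan = makeSamplingPlan(d, config@m * config@k, config@alpha,
                                     config@seed),
             partition = partitionGroups(config@m, config@k,
                                         config@seed + 1L))
    }
}

#' Encode cells into long and short hashes
#'
#' The full encoding pipeline for one or more cells: optional
#' centralization, then the configured scheme's long hash, plus the short
#' hash used by multi-probe search. For SimHash the short table is the long
#' table (no pseudo-hash exists).
#'
#' @param x A genes x cells matrix (or single numeric vector, or a
#'   `SummarizedExperiment` whose first assay holds expression).
#' @param config A [HashConfig-class].
#' @param structures Optional pre-built [hashStructures()] (they are built
#'   from `config` and the gene count when omitted).
#' @return A list with `long` and `short` integer 0/1 matrices (cells in
#'   rows) and the `structures` used.
#' @examples
#' x <- matrix(rpois(200, 5), nrow = 20)
#' enc <- encodeCells(x, HashConfig("densefly", m = 4, k = 8, seed = 1))
#' dim(enc$long); dim(enc$short)
#' @export
encodeCells <- function(x, config, structures = NULL) {
    stopifnot(methods::is(config, "HashConfig"))
    if (!is.matrix(x) && !methods::is(x, "Matrix") &&
        !methods::is(x, "SummarizedExperiment"))
        x <- matrix(.asExpressionVector(x), ncol = 1L)
    x <- .asExpressionMatrix(x)
    d <- nrow(x)
    if (config@method != "simhash" && floor(config@alpha * d) < 1)
        stop("floor(alpha * d) must be at least 1 (alpha = ", config@alpha,
             ", d = ", d, ")", call. = FALSE)
    if (is.null(structures)) structures <- hashStructures(config, d)
    if (config@centralize) x <- centralizeExpression(x)
    if (config@method == "simhash") {
        long <- simhashEncode(x, structures$basis)
        short <- long
    } else {
        a <- computeActivations(x, structures$plan)
        long <- switch(config@method,
                       flyhash = flyhashEncode(a, structures$partition),
                       densefly = denseflyEncode(a, structures$partition))
        short <- pseudoHash(a, structures$partition)
    }
    rownames(long) <- colnames(x)
    rownames(short) <- colnames(x)
    list(long = long, short = short, structures = structures)
}
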