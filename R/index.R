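#' Hamming distance between two bit vectors
#'
#' @param a,b Binary 0/1 vectors of equal length.
#' @return Integer count of positions where the bits differ.
#' @examples
#' hammingDistance(c(0, 1, 0, 1), c(1, 1, 0, 0))
#' @export
hammingDistance <- function(a, b) {
    if (length(a) != length(b))
        stop("bit vectors differ in length: ", length(a), " vs ", length(b),
             call. = FALSE)
    sum(a != b)
}

# Hamming distances from every row of bit matrix H (n x B) to each column
# of Q (n_q x B given as rows): returns n x n_q matrix. Uses the identity
# d(h, q) = |h| + |q| - 2 h.q for 0/1 vectors, computed via BLAS.
.hammingToAll <- function(H, Qrows) {
    rs <- rowSums(H)
    qs <- rowSums(Qrows)
    D <- -2 * (H %*% t(Qrows))
    D <- D + outer(rs, qs, "+")
    round(D)
}

# Internal constructor bypassing re-encoding (rows already encoded).
.newHashIndex <- function(cellIds, labels, long, short, config, d,
                          structures) {
    methods::new("HashIndex",
        cellIds = as.character(cellIds),
        labels = if (is.null(labels)) character(0) else as.character(labels),
        longHashes = long, shortHashes = short,
        config = config, d = as.integer(d), structures = structures)
}

#' Build a reference hash index
#'
#' Encodes every reference cell (centralizing first when configured) into
#' long and short hashes sharing one set of seeded random structures, and
#' stores them with the cell identifiers and optional cell-type labels.
#'
#' @param x A genes x cells expression matrix, or a `SummarizedExperiment` /
#'   `SingleCellExperiment` whose first assay holds expression (labels are
#'   then taken from the `group` column of `colData` unless supplied).
#' @param config A [HashConfig-class].
#' @param labels Optional character vector of per-cell labels.
#' @return A [HashIndex-class].
#' @examples
#' x <- matrix(rpois(1000, 5), nrow = 50,
#'             dimnames = list(NULL, paste0("cell", 1:20)))
#' idx <- buildIndex(x, HashConfig("densefly", m = 4, k = 8, seed = 1))
#' idx
#' @export
buildIndex <- function(x, config, labels = NULL) {
    labels <- .resolveLabels(x, labels)
    x <- .asExpressionMatrix(x)
    n <- ncol(x)
    if (!is.null(labels) && length(labels) != n)
        stop("labels length (", length(labels),
             ") does not match cell count (", n, ")", call. = FALSE)
    ids <- colnames(x)
    if (is.null(ids)) ids <- paste0("cell_", seq_len(n))
    enc <- encodeCells(x, config)
    .newHashIndex(ids, labels, enc$long, enc$short, config, nrow(x),
                  enc$structures)
}

# Two-stage search over already-encoded queries. refLong/refShort are the
# reference tables; qLong/qShort have one query per row. Returns a
# data.frame (nearest index, distance, radius, candidate count).
.searchEncoded <- function(refLong, refShort, qLong, qShort,
                           initialRadius = 2L) {
    nRef <- nrow(refShort)
    M <- ncol(refShort)
    shortD <- .hammingToAll(refShort, qShort)   # nRef x nQ
    longD <- .hammingToAll(refLong, qLong)      # nRef x nQ
    nQ <- nrow(qShort)
    out <- data.frame(nearest = integer(nQ), long_distance = integer(nQ),
                      radius_used = integer(nQ), candidate_count = integer(nQ))
    for (q in seq_len(nQ)) {
        r <- initialRadius
        repeat {
            if (r >= M) {
                cand <- seq_len(nRef)
                r <- M
                break
            }
            cand <- which(shortD[, q] <= r)
            if (length(cand)) break
            r <- if (r == 0L) 1L else 2L * r
        }
        ld <- longD[cand, q]
        best <- cand[which.min(ld)]  # which.min: lowest index wins ties
        out$nearest[q] <- best
        out$long_distance[q] <- as.integer(ld[which.min(ld)])
        out$radius_used[q] <- as.integer(r)
        out$candidate_count[q] <- length(cand)
    }
    out
}

#' Two-stage multi-probe nearest-neighbor query
#'
#' For each query cell: encode it with the index's structures, find all
#' reference cells within a Hamming radius of its short hash (starting at
#' `initialRadius`; an empty candidate set doubles the radius, 0 promoting
#' to 1, until candidates appear or the radius reaches the short-hash width,
#' at which point every reference is a candidate), then return the candidate
#' with the minimal long-hash distance, ties broken by the lowest reference
#' index. For SimHash the short table equals the long table, so this is a
#' single-stage exact Hamming search.
#'
#' @param index A [HashIndex-class].
#' @param query A numeric vector (one cell) or genes x cells matrix.
#' @param initialRadius Starting short-hash radius. The default 2 keeps the
#'   candidate ball small (211 of the 2^20 short-hash buckets at m = 20)
#'   while tolerating the few short-hash bit flips that technical noise such
#'   as batch effects induces; 0 requests an exact short-hash match first.
#' @return A data.frame with one row per query: `query_id`, `nearest_id`,
#'   `nearest_label` (NA when the index is unlabeled), `long_distance`,
#'   `radius_used`, `candidate_count`.
#' @export
multiprobeQuery <- function(index, query, initialRadius = 2L) {
    stopifnot(methods::is(index, "HashIndex"))
    if (initialRadius < 0)
        stop("initialRadius must be non-negative", call. = FALSE)
    if (!is.matrix(query) && !methods::is(query, "Matrix") &&
        !methods::is(query, "SummarizedExperiment"))
        query <- matrix(.asExpressionVector(query), ncol = 1L)
    query <- .asExpressionMatrix(query)
    if (nrow(query) != index@d)
        stop("query has ", nrow(query), " genes but the index was built on ",
             index@d, call. = FALSE)
    enc <- encodeCells(query, index@config, structures = index@structures)
    res <- .searchEncoded(index@longHashes, index@shortHashes,
                          enc$long, enc$short,
                          initialRadius = as.integer(initialRadius))
    qids <- colnames(query)
    if (is.null(qids)) qids <- paste0("query_", seq_len(ncol(query)))
    data.frame(
        query_id = qids,
        nearest_id = index@cellIds[res$nearest],
        nearest_label = if (length(index@labels))
            index@labels[res$nearest] else NA_character_,
        long_distance = res$long_distance,
        radius_used = res$radius_used,
        candidate_count = res$candidate_count,
        stringsAsFactors = FALSE)
}

#' Classify query cells by nearest reference neighbor
#'
#' Returns the cell-type label of each query's nearest reference cell under
#' the two-stage multi-probe search (top-1 neighbor only).
#'
#' @inheritParams multiprobeQuery
#' @return Character vector of predicted labels, one per query cell.
#' @export
classifyCells <- function(index, query, initialRadius = 2L) {
    stopifnot(methods::is(index, "HashIndex"))
    if (!length(index@labels))
        stop("index has no cell-type labels; build it with labels to classify",
             call. = FALSE)
    multiprobeQuery(index, query, initialRadius)$nearest_label
}

#' Write query results as TSV
#'
#' @param results A data.frame from [multiprobeQuery()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeQueryResults <- function(results, path) {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

## ---- index serialization ------------------------------------------------

.IDX_MAGIC <- "SCDFIDX1"

.writeStr <- function(con, s) {
    r <- charToRaw(enc2utf8(s))
    writeBin(length(r), con, size = 4L)
    writeBin(r, con)
}

.readStr <- function(con) {
    n <- readBin(con, "integer", 1L, size = 4L)
    rawToChar(readBin(con, "raw", n))
}

.writeBits <- function(con, H) {
    writeBin(nrow(H), con, size = 4L)
    writeBin(ncol(H), con, size = 4L)
    v <- as.integer(t(H))          # row-major
    pad <- (-length(v)) %% 8L
    if (pad) v <- c(v, integer(pad))
    writeBin(packBits(as.logical(v), type = "raw"), con)
}

.readBits <- function(con) {
    nr <- readBin(con, "integer", 1L, size = 4L)
    nc <- readBin(con, "integer", 1L, size = 4L)
    nbits <- nr * nc
    nbytes <- ceiling(nbits / 8)
    bits <- as.integer(rawToBits(readBin(con, "raw", nbytes)))[seq_len(nbits)]
    matrix(bits, nrow = nr, ncol = nc, byrow = TRUE)
}

#' Serialize a hash index to a single file
#'
#' Writes a versioned binary container: a magic header, the configuration
#' (method, m, k, alpha, seed, centralization, SimHash width), the gene
#' count, cell identifiers and labels, and the bit-packed long and short
#' hash tables. The seeded structures are not stored; they are regenerated
#' bit-exactly from the configuration on read, so round-trips are exact.
#'
#' @param index A [HashIndex-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [readHashIndex()]
#' @export
writeHashIndex <- function(index, path) {
    stopifnot(methods::is(index, "HashIndex"))
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(.IDX_MAGIC), con)
    writeBin(1L, con, size = 4L)                 # format version
    cfg <- index@config
    .writeStr(con, cfg@method)
    writeBin(c(cfg@m, cfg@k), con, size = 4L)
    writeBin(cfg@alpha, con, size = 8L)
    writeBin(cfg@seed, con, size = 4L)
    writeBin(as.integer(cfg@centralize), con, size = 4L)
    .writeStr(con, cfg@simhashBits)
    writeBin(index@d, con, size = 4L)
    n <- length(index@cellIds)
    writeBin(n, con, size = 4L)
    for (s in index@cellIds) .writeStr(con, s)
    writeBin(length(index@labels), con, size = 4L)
    for (s in index@labels) .writeStr(con, s)
    .writeBits(con, index@longHashes)
    .writeBits(con, index@shortHashes)
    invisible(path)
}

#' Read a serialized hash index
#'
#' @param path File written by [writeHashIndex()].
#' @return A [HashIndex-class] identical (bit-for-bit in all hash tables,
#'   identifiers and configuration) to the one written.
#' @export
readHashIndex <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- rawToChar(readBin(con, "raw", nchar(.IDX_MAGIC)))
    if (!identical(magic, .IDX_MAGIC))
        stop("not a hash index file: ", path, call. = FALSE)
    ver <- readBin(con, "integer", 1L, size = 4L)
    if (ver != 1L)
        stop("unsupported index format version: ", ver, call. = FALSE)
    method <- .readStr(con)
    mk <- readBin(con, "integer", 2L, size = 4L)
    alpha <- readBin(con, "double", 1L, size = 8L)
    seed <- readBin(con, "integer", 1L, size = 4L)
    centralize <- as.logical(readBin(con, "integer", 1L, size = 4L))
    simhashBits <- .readStr(con)
    cfg <- HashConfig(method, m = mk[1L], k = mk[2L], alpha = alpha,
                      seed = seed, centralize = centralize,
                      simhashBits = simhashBits)
    d <- readBin(con, "integer", 1L, size = 4L)
    n <- readBin(con, "integer", 1L, size = 4L)
    ids <- vapply(seq_len(n), function(i) .readStr(con), character(1))
    nl <- readBin(con, "integer", 1L, size = 4L)
    labels <- if (nl) vapply(seq_len(nl), function(i) .readStr(con),
                             character(1)) else NULL
    long <- .readBits(con)
    short <- .readBits(con)
    .newHashIndex(ids, labels, long, short, cfg, d, hashStructures(cfg, d))
}
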