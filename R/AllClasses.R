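#' @import methods
NULL

#' Hashing configuration
#'
#' An S4 class holding the parameters of a locality-sensitive hash encoder.
#' All three schemes map a centralized expression vector of length `d` to a
#' binary "long hash"; the fly-inspired schemes additionally admit an m-bit
#' "short hash" (pseudo-hash) used for multi-probe candidate retrieval.
#'
#' @slot method One of `"simhash"`, `"flyhash"`, `"densefly"`.
#' @slot m Number of shuffle groups (also the short-hash width), a positive
#'   integer.
#' @slot k Winner-take-all group size, often called the hash size. The long
#'   hash has `m * k` bits for the fly schemes.
#' @slot alpha Sampling rate in (0, 1]: each activation sums
#'   `floor(alpha * d)` randomly chosen genes. Ignored by SimHash.
#' @slot seed Integer seed from which every random structure (projection
#'   basis, sampling plan, group partition) is regenerated deterministically.
#' @slot centralize Logical; subtract each cell's mean expression before
#'   encoding (default `TRUE`).
#' @slot simhashBits `"mk"` (default) gives SimHash the same long-hash width
#'   `m * k` as the fly schemes; `"k"` uses only `k` projections, matching
#'   benchmark setups where only the fly schemes get the m-fold embedding.
#'
#' @seealso [HashConfig()] for the user-facing constructor.
#' @exportClass HashConfig
setClass("HashConfig",
    representation(
        method = "character",
        m = "integer",
        k = "integer",
        alpha = "numeric",
        seed = "integer",
        centralize = "logical",
        simhashBits = "character"
    )
)

setValidity("HashConfig", function(object) {
    msg <- character(0)
    if (length(object@method) != 1L ||
        !object@method %in% c("simhash", "flyhash", "densefly"))
        msg <- c(msg, "method must be one of 'simhash', 'flyhash', 'densefly'")
    if (length(object@m) != 1L || is.na(object@m) || object@m < 1L)
        msg <- c(msg, "m must be a positive integer")
    if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
        msg <- c(msg, "k must be a positive integer")
    if (length(object@alpha) != 1L || is.na(object@alpha) ||
        object@alpha <= 0 || object@alpha > 1)
        msg <- c(msg, "alpha must lie in (0, 1]")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "seed must be a single integer")
    if (length(object@centralize) != 1L || is.na(object@centralize))
        msg <- c(msg, "centralize must be TRUE or FALSE")
    if (length(object@simhashBits) != 1L ||
        !object@simhashBits %in% c("mk", "k"))
        msg <- c(msg, "simhashBits must be 'mk' or 'k'")
    if (length(msg)) msg else TRUE
})

#' Construct a hashing configuration
#'
#' @param method Hashing scheme: `"densefly"`, `"flyhash"` or `"simhash"`.
#' @param m Number of shuffle groups (short-hash width). Default 20, the
#'   setting used throughout the benchmark experiments.
#' @param k Hash size (winner-take-all group size).
#' @param alpha Sampling rate for the fly schemes; each of the `m * k`
#'   activations sums `floor(alpha * d)` genes. Default 0.1.
#' @param seed Integer seed for the encoder's random structures.
#' @param centralize Subtract the per-cell mean expression before encoding.
#' @param simhashBits SimHash long-hash width: `"mk"` (equal width to the fly
#'   schemes, default) or `"k"`.
#'
#' @return A [HashConfig-class] object.
#' @examples
#' cfg <- HashConfig("densefly", m = 20, k = 64, alpha = 0.1, seed = 1)
#' cfg
#' @export
HashConfig <- function(method = c("densefly", "flyhash", "simhash"),
                       m = 20, k = 64, alpha = 0.1, seed = 1,
                       centralize = TRUE, simhashBits = c("mk", "k")) {
    method <- match.arg(method)
    simhashBits <- match.arg(simhashBits)
    new("HashConfig",
        method = method, m = as.integer(m), k = as.integer(k),
        alpha = as.numeric(alpha), seed = as.integer(seed),
        centralize = as.logical(centralize), simhashBits = simhashBits)
}

#' Reference hash index
#'
#' An S4 class storing a hashed reference database of cells: the long and
#' short binary hash tables, the cell identifiers and (optionally) their
#' cell-type labels, plus the configuration and seeded random structures
#' needed to encode queries identically. For SimHash the short table is the
#' long table (there is no pseudo-hash) and multi-probe search degrades to a
#' single-stage scan.
#'
#' @slot cellIds Character vector of reference cell identifiers.
#' @slot labels Character vector of cell-type labels (length 0 if unlabeled).
#' @slot longHashes Integer 0/1 matrix, cells in rows, one column per long
#'   hash bit.
#' @slot shortHashes Integer 0/1 matrix, cells in rows, `m` columns for the
#'   fly schemes (equal to `longHashes` for SimHash).
#' @slot config The [HashConfig-class] used for encoding.
#' @slot d Number of genes the encoder was built for.
#' @slot structures Seeded random structures (projection basis, or sampling
#'   plan and group partition) shared by reference and query encoding.
#'
#' @seealso [buildIndex()], [multiprobeQuery()], [writeHashIndex()]
#' @exportClass HashIndex
setClass("HashIndex",
    representation(
        cellIds = "character",
        labels = "character",
        longHashes = "matrix",
        shortHashes = "matrix",
        config = "HashConfig",
        d = "integer",
        structures = "list"
    )
)

setValidity("HashIndex", function(object) {
    msg <- character(0)
    n <- length(object@cellIds)
    if (n < 1L)
        msg <- c(msg, "index must contain at least one reference cell")
    if (anyDuplicated(object@cellIds))
        msg <- c(msg, "cell identifiers must be unique")
    if (nrow(object@longHashes) != n || nrow(object@shortHashes) != n)
        msg <- c(msg, "hash tables must have one row per reference cell")
    if (!length(object@labels) %in% c(0L, n))
        msg <- c(msg, "labels must be empty or one per reference cell")
    if (ncol(object@longHashes) < ncol(object@shortHashes))
        msg <- c(msg, "long hashes cannot be narrower than short hashes")
    bits <- c(object@longHashes, object@shortHashes)
    if (length(bits) && !all(bits %in% c(0L, 1L)))
        msg <- c(msg, "hash tables must be binary")
    if (length(msg)) msg else TRUE
})

#' Cross-validation result
#'
#' Per-fold Cohen's kappa scores from a k-fold cell-mapping cross-validation,
#' together with the hashing configuration that produced them.
#'
#' @slot foldScores Numeric vector of per-fold kappa values, each in
#'   \eqn{[-1, 1]}.
#' @slot config The [HashConfig-class] evaluated.
#' @slot tag Free-text experiment tag (e.g. `"selfmap"`, `"batch:1to2"`).
#'
#' @seealso [crossValidate()], [foldScores()], [meanScore()]
#' @exportClass CVResult
setClass("CVResult",
    representation(
        foldScores = "numeric",
        config = "HashConfig",
        tag = "character"
    )
)

setValidity("CVResult", function(object) {
    msg <- character(0)
    if (length(object@foldScores) < 1L)
        msg <- c(msg, "at least one fold score required")
    if (any(!is.finite(object@foldScores)) ||
        any(object@foldScores < -1 - 1e-12) ||
        any(object@foldScores > 1 + 1e-12))
        msg <- c(msg, "fold scores must be finite values in [-1, 1]")
    if (length(msg)) msg else TRUE
})
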