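#' @rdname HashIndex-class
#' @export
setMethod("cellIds", "HashIndex", function(x) x@cellIds)

#' @rdname HashIndex-class
#' @export
setMethod("cellLabels", "HashIndex", function(x) {
    if (length(x@labels)) x@labels else NULL
})

#' @rdname HashIndex-class
#' @export
setMethod("longHashes", "HashIndex", function(x) x@longHashes)

#' @rdname HashIndex-class
#' @export
setMethod("shortHashes", "HashIndex", function(x) x@shortHashes)

#' @rdname HashIndex-class
#' @export
setMethod("hashConfig", "HashIndex", function(x) x@config)

#' @rdname CVResult-class
#' @export
setMethod("foldScores", "CVResult", function(x) x@foldScores)

#' @rdname CVResult-class
#' @export
setMethod("meanScore", "CVResult", function(x) mean(x@foldScores))

#' @rdname embeddingSize
#' @export
setMethod("embeddingSize", "HashConfig", function(x) {
    if (x@method == "simhash" && x@simhashBits == "k") x@k else x@m * x@k
})

setMethod("show", "HashConfig", function(object) {
    cat("HashConfig:", object@method,
        sprintf("(m = %d, k = %d, alpha = %g, seed = %d)",
                object@m, object@k, object@alpha, object@seed), "\n")
    cat("  long hash:", embeddingSize(object), "bits;",
        if (object@method == "simhash") "single-stage search"
        else sprintf("short hash: %d bits", object@m), "\n")
    cat("  centralize:", object@centralize, "\n")
})

setMethod("show", "HashIndex", function(object) {
    cat("HashIndex of", length(object@cellIds), "cells over",
        object@d, "genes\n")
    cat("  long table:", nrow(object@longHashes), "x",
        ncol(object@longHashes), " short table:",
        nrow(object@shortHashes), "x", ncol(object@shortHashes), "\n")
    if (length(object@labels))
        cat("  labels:", paste(utils::head(sort(unique(object@labels)), 6),
                               collapse = ", "),
            if (length(unique(object@labels)) > 6) "..." else "", "\n")
    show(object@config)
})

setMethod("show", "CVResult", function(object) {
    cat("CVResult [", object@tag, "]: mean kappa =",
        format(mean(object@foldScores), digits = 4), "over",
        length(object@foldScores), "folds\n")
    cat("  folds:", paste(format(object@foldScores, digits = 3),
                          collapse = ", "), "\n")
})
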