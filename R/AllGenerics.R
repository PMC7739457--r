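#' @rdname HashIndex-class
#' @param x A `HashIndex` or `CVResult` object.
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname HashIndex-class
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' @rdname HashIndex-class
#' @export
setGeneric("longHashes", function(x) standardGeneric("longHashes"))

#' @rdname HashIndex-class
#' @export
setGeneric("shortHashes", function(x) standardGeneric("shortHashes"))

#' @rdname HashIndex-class
#' @export
setGeneric("hashConfig", function(x) standardGeneric("hashConfig"))

#' @rdname CVResult-class
#' @export
setGeneric("foldScores", function(x) standardGeneric("foldScores"))

#' @rdname CVResult-class
#' @export
setGeneric("meanScore", function(x) standardGeneric("meanScore"))

#' Long-hash width implied by a configuration
#'
#' `m * k` for the fly schemes; for SimHash either `m * k` or `k` depending
#' on the `simhashBits` setting.
#'
#' @param x A [HashConfig-class].
#' @return Integer number of long-hash bits.
#' @export
setGeneric("embeddingSize", function(x) standardGeneric("embeddingSize"))
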