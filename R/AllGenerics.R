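#' Accessors for QuantMatrix and ZMatrix
#'
#' \code{areas()} returns the peak-area matrix, \code{detected()} the logical
#' detection mask, \code{zValues()} the standardized log-area matrix of a
#' \linkS4class{ZMatrix} (NA where not detected), and \code{proteinIds()} /
#' \code{sampleIds()} the row and column identifiers.
#'
#' @param x a \linkS4class{QuantMatrix} or \linkS4class{ZMatrix}.
#' @return a matrix or character vector; see above.
#' @name quant-accessors
#' @examples
#' qm <- QuantMatrix(matrix(c(2, 4, 0, 8), 2, 2,
#'     dimnames = list(c("p1", "p2"), c("s1", "s2"))))
#' areas(qm)
#' proteinIds(qm)
NULL

#' @rdname quant-accessors
#' @export
setGeneric("areas", function(x) standardGeneric("areas"))

#' @rdname quant-accessors
#' @export
setGeneric("detected", function(x) standardGeneric("detected"))

#' @rdname quant-accessors
#' @export
setGeneric("zValues", function(x) standardGeneric("zValues"))

#' @rdname quant-accessors
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname quant-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname quant-accessors
setMethod("areas", "QuantMatrix", function(x) assay(x, "area"))

#' @rdname quant-accessors
setMethod("detected", "SummarizedExperiment",
          function(x) assay(x, "detected"))

#' @rdname quant-accessors
setMethod("zValues", "ZMatrix", function(x) assay(x, "z"))

#' @rdname quant-accessors
setMethod("proteinIds", "SummarizedExperiment", function(x) rownames(x))

#' @rdname quant-accessors
setMethod("sampleIds", "SummarizedExperiment", function(x) colnames(x))
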