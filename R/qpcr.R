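## Relative mRNA expression from qPCR threshold cycles.

#' Relative expression from threshold cycles
#'
#' Classic housekeeping-gene normalization:
#' \eqn{2^{-(Ct_{target} - Ct_{reference})} \times 100}, i.e. 100 when
#' target and reference amplify at the same cycle, halving per extra
#' cycle. Undetermined target Ct (no amplification, encoded as \code{NA})
#' yields expression 0 -- absence must be representable -- and is flagged
#' in the \code{"undetermined"} attribute.
#'
#' @param ctTarget numeric vector of target-gene threshold cycles;
#'   \code{NA} = undetermined.
#' @param ctReference threshold cycles of the reference (housekeeping)
#'   gene, recycled to the length of \code{ctTarget}.
#' @return numeric vector of relative expression values (percent of the
#'   reference gene), with attribute \code{undetermined}.
#' @examples
#' relativeExpression(c(25, 26, 23), 25)   # 100, 50, 400
#' @export
relativeExpression <- function(ctTarget, ctReference) {
    undet <- is.na(ctTarget)
    if (any(is.na(ctReference)))
        stop("reference Ct must not be undetermined")
    if (any(!is.finite(ctTarget[!undet])) || any(!is.finite(ctReference)))
        stop("Ct values must be finite")
    if (any(ctTarget[!undet] <= 0) || any(ctReference <= 0))
        stop("Ct values must be positive cycle numbers")
    out <- 2^(-(ctTarget - ctReference)) * 100
    out[undet] <- 0
    attr(out, "undetermined") <- undet
    out
}

#' Relative expression for a long-format Ct table
#'
#' @param ct data.frame with columns \code{sample_id}, \code{gene},
#'   \code{ct} (NA = undetermined); one row per sample x gene.
#' @param referenceGene housekeeping gene name (default \code{"GAPDH"});
#'   must be measured in every sample.
#' @return data.frame \code{sample_id}, \code{gene},
#'   \code{relative_expression}, \code{undetermined} for all non-reference
#'   genes.
#' @export
relativeExpressionTable <- function(ct, referenceGene = "GAPDH") {
    ct <- as.data.frame(ct)
    stopifnot(all(c("sample_id", "gene", "ct") %in% colnames(ct)))
    ref <- ct[ct$gene == referenceGene, ]
    if (anyDuplicated(ref$sample_id))
        stop("multiple reference measurements for sample ",
             ref$sample_id[duplicated(ref$sample_id)][1L])
    tgt <- ct[ct$gene != referenceGene, ]
    miss <- setdiff(unique(tgt$sample_id), ref$sample_id)
    if (length(miss))
        stop("no ", referenceGene, " measurement for sample(s): ",
             paste(miss, collapse = ", "))
    ref_ct <- setNames(ref$ct, ref$sample_id)
    expr <- relativeExpression(tgt$ct, ref_ct[tgt$sample_id])
    data.frame(sample_id = tgt$sample_id,
               gene = tgt$gene,
               relative_expression = as.numeric(expr),
               undetermined = attr(expr, "undetermined"),
               row.names = NULL)
}
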