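## Delta-Z interactor calling with knockout-background subtraction, and
## interactome set algebra.

.background_of <- c(WT = "WT_TG2KO", APP23 = "APP23_TG2KO")

#' Z-transform a quantification matrix
#'
#' Each detected peak area is natural-log transformed and standardized by
#' subtracting the mean and dividing by the population standard deviation
#' (divide by N, not N-1) of \emph{all} detected entries of the matrix
#' jointly. The detection mask is preserved; nondetected entries stay
#' \code{NA}. The population here is the IP experiment being normalized, so
#' callers should subset to the relevant cohorts first (see
#' [interactorScreen()]).
#'
#' @param x a \linkS4class{QuantMatrix} with all detected values > 0 and at
#'   least two detected entries.
#' @return a \linkS4class{ZMatrix}; the log-population mean and SD are in
#'   \code{metadata()} as \code{mu} and \code{sigma}.
#' @section Errors:
#' A zero population SD (all detected values equal) raises
#' \code{"degenerate population"}; nonpositive detected values are an error.
#' @examples
#' qm <- QuantMatrix(matrix(c(exp(1), exp(-1)), 1, 2,
#'     dimnames = list("p", c("a", "b"))))
#' zValues(zTransform(qm))   # +1, -1
#' @export
zTransform <- function(x) {
    stopifnot(is(x, "QuantMatrix"))
    a <- areas(x)
    d <- detected(x)
    v <- a[d]
    if (length(v) < 2L) stop("need at least 2 detected values")
    if (any(v <= 0)) stop("detected value <= 0 cannot be log-transformed")
    lv <- log(v)
    mu <- mean(lv)
    sigma <- sqrt(mean((lv - mu)^2))        # population SD
    if (sigma < 1e-12) stop("degenerate population: zero variance")
    z <- matrix(NA_real_, nrow(a), ncol(a), dimnames = dimnames(a))
    z[d] <- (log(a[d]) - mu) / sigma
    se <- SummarizedExperiment(
        assays = SimpleList(z = z, detected = d),
        colData = colData(x))
    out <- new("ZMatrix", se)
    metadata(out) <- list(mu = mu, sigma = sigma)
    out
}

#' Impute nondetected background-cohort values at the detection floor
#'
#' Background (bait-knockout) IPs define nonspecific binding; a protein that
#' is absent there is evidence \emph{for} specific association, so missing
#' background values are set to the matrix detection floor (the minimum
#' detected value of the whole matrix) before Z-transformation. Values
#' missing in the bait-positive cohort are never imputed -- they only clear
#' the detected-in-all flag downstream.
#'
#' @param x a \linkS4class{QuantMatrix} with sample metadata attached.
#' @param phenotype \code{"WT"} or \code{"APP23"}: the bait-positive
#'   genotype whose knockout counterpart is the background.
#' @return \code{x} with background nondetections filled at the floor and
#'   marked detected; the number of imputed cells is reported in a message.
#' @export
imputeBackgroundFloor <- function(x, phenotype = c("WT", "APP23")) {
    phenotype <- match.arg(phenotype)
    a <- areas(x)
    d <- detected(x)
    if (!all(d) && !any(d)) stop("matrix has no detected values")
    floor_val <- min(a[d])
    bg <- colData(x)$genotype == .background_of[[phenotype]]
    if (!any(bg)) stop("no background (", .background_of[[phenotype]],
                       ") samples present")
    fill <- !d & matrix(bg, nrow(a), ncol(a), byrow = TRUE)
    if (any(fill)) {
        a[fill] <- floor_val
        d[fill] <- TRUE
        message("imputed ", sum(fill),
                " background nondetection(s) at floor ",
                format(floor_val))
    }
    QuantMatrix(a, d, sampleData = colData(x))
}

#' Mean Z-score difference between bait-positive and background IPs
#'
#' For each protein, replicate-wise differences
#' \eqn{\Delta Z_r = Z^{+}_r - Z^{-}_r} are formed between the bait-positive
#' cohort (genotype = \code{phenotype}) and its knockout background,
#' replicates aligned by sorted replicate number, and averaged. Animals are
#' not biologically paired: because the statistic is the mean difference,
#' the arbitrary pairing is inconsequential (mean dZ = mean Z+ - mean Z-).
#' Nondetected entries are excluded from the cohort means; proteins with any
#' nondetected bait-positive replicate carry \code{detected_in_all = FALSE}.
#'
#' @param z a \linkS4class{ZMatrix} (from [zTransform()]) whose
#'   \code{colData} carries the sample sheet.
#' @param phenotype \code{"WT"} or \code{"APP23"}.
#' @param sheet optional sample sheet overriding \code{colData(z)}.
#' @return a [S4Vectors::DataFrame] with \code{protein_id},
#'   \code{phenotype}, \code{delta_z_mean}, \code{detected_in_all} and
#'   \code{n_replicates}.
#' @export
deltaZ <- function(z, phenotype = c("WT", "APP23"), sheet = NULL) {
    phenotype <- match.arg(phenotype)
    stopifnot(is(z, "ZMatrix"))
    cd <- if (is.null(sheet)) colData(z) else
        validateSampleSheet(as.data.frame(sheet))[sampleIds(z), ]
    if (!"genotype" %in% colnames(cd))
        stop("sample metadata with a 'genotype' column is required")
    is_ip <- if ("assay" %in% colnames(cd)) cd$assay == "IP" else
        rep(TRUE, ncol(z))
    pos <- which(is_ip & cd$genotype == phenotype)
    bg <- which(is_ip & cd$genotype == .background_of[[phenotype]])
    if (!length(pos)) stop("no IP samples for phenotype ", phenotype)
    if (length(pos) != length(bg))
        stop("unequal cohort sizes: ", length(pos), " bait-positive vs ",
             length(bg), " background")
    pos <- pos[order(cd$replicate[pos])]
    bg <- bg[order(cd$replicate[bg])]
    zv <- zValues(z)
    det <- detected(z)
    zp <- zv[, pos, drop = FALSE]
    zb <- zv[, bg, drop = FALSE]
    mean_pos <- rowMeans(zp, na.rm = TRUE)
    mean_bg <- rowMeans(zb, na.rm = TRUE)
    dzm <- mean_pos - mean_bg
    dzm[is.nan(dzm)] <- NA_real_
    DataFrame(
        protein_id = proteinIds(z),
        phenotype = phenotype,
        delta_z_mean = unname(dzm),
        detected_in_all = unname(rowSums(det[, pos, drop = FALSE]) ==
                                     length(pos)),
        n_replicates = length(pos))
}

#' Call bait-specific interactors from Delta-Z statistics
#'
#' The mean Delta-Z is mapped onto the upper tail of the standard normal,
#' \eqn{p = 1 - \Phi(\bar{\Delta Z})}; a protein is called a specific
#' interactor when \eqn{p \le \alpha} \emph{and} it was detected in every
#' bait-positive replicate. With \code{scale = "paired"} the statistic is
#' standardized as a paired z-test, multiplying by \eqn{\sqrt{n/2}} (the
#' mean of n differences of two unit-variance Z-scores has variance 2/n);
#' the default maps the mean Delta-Z onto the normal curve directly.
#'
#' @param dz result of [deltaZ()].
#' @param alpha significance level in (0, 1).
#' @param strict if \code{TRUE}, require \eqn{p < \alpha} rather than
#'   \eqn{p \le \alpha} at the boundary.
#' @param scale \code{"none"} (default) or \code{"paired"}; see above.
#' @param adjust \code{"none"} (default, raw p) or \code{"BH"} for
#'   Benjamini-Hochberg adjustment, in which case calling uses the adjusted
#'   values.
#' @return a [S4Vectors::DataFrame] of per-protein calls sorted by p-value,
#'   with columns \code{protein_id}, \code{phenotype}, \code{delta_z_mean},
#'   \code{p_value}, optionally \code{p_adjusted}, \code{detected_in_all},
#'   \code{called}.
#' @examples
#' dz <- DataFrame(protein_id = c("a", "b"), phenotype = "WT",
#'                 delta_z_mean = c(0, 3), detected_in_all = TRUE,
#'                 n_replicates = 5L)
#' callInteractors(dz)
#' @export
callInteractors <- function(dz, alpha = 0.05, strict = FALSE,
                            scale = c("none", "paired"),
                            adjust = c("none", "BH")) {
    scale <- match.arg(scale)
    adjust <- match.arg(adjust)
    if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
        stop("alpha must be in (0, 1)")
    stat <- dz$delta_z_mean
    if (scale == "paired") stat <- stat * sqrt(dz$n_replicates / 2)
    p <- 1 - stats::pnorm(stat)
    p_use <- p
    out <- DataFrame(protein_id = dz$protein_id,
                     phenotype = dz$phenotype,
                     delta_z_mean = dz$delta_z_mean,
                     p_value = p)
    if (adjust == "BH") {
        out$p_adjusted <- p_use <- stats::p.adjust(p, method = "BH")
    }
    pass <- if (strict) p_use < alpha else p_use <= alpha
    out$detected_in_all <- dz$detected_in_all
    out$called <- !is.na(pass) & pass & dz$detected_in_all
    out[order(out$p_value), ]
}

#' Screen one phenotype pair for bait-specific interactors
#'
#' End-to-end wrapper for one bait-positive/knockout IP pair: subsets the
#' matrix to the pair's IP samples, imputes background nondetections at the
#' detection floor, Z-transforms over the pair's detected population, forms
#' mean Delta-Z per protein and calls interactors.
#'
#' @param x a \linkS4class{QuantMatrix} covering the IP experiment.
#' @param phenotype \code{"WT"} or \code{"APP23"}.
#' @param sheet sample sheet; defaults to \code{colData(x)}.
#' @param alpha,strict,scale,adjust passed to [callInteractors()].
#' @param impute impute background nondetections at the floor (default TRUE).
#' @return the [callInteractors()] DataFrame; the Z-population mean/SD are
#'   attached as metadata columns of the result's \code{metadata()}.
#' @export
interactorScreen <- function(x, phenotype = c("WT", "APP23"), sheet = NULL,
                             alpha = 0.05, strict = FALSE,
                             scale = c("none", "paired"),
                             adjust = c("none", "BH"), impute = TRUE) {
    phenotype <- match.arg(phenotype)
    if (!is.null(sheet)) x <- attachSampleSheet(x, sheet)
    cd <- colData(x)
    if (!all(c("genotype", "assay") %in% colnames(cd)))
        stop("sample metadata (genotype, assay) required; ",
             "attach a sample sheet")
    keep <- cd$assay == "IP" &
        cd$genotype %in% c(phenotype, .background_of[[phenotype]])
    if (!any(keep)) stop("no IP samples for phenotype ", phenotype)
    x <- x[, keep]
    if (impute) x <- imputeBackgroundFloor(x, phenotype)
    z <- zTransform(x)
    calls <- callInteractors(deltaZ(z, phenotype), alpha = alpha,
                             strict = strict, scale = scale,
                             adjust = adjust)
    metadata(calls) <- metadata(z)
    calls
}

#' Compare two interactomes
#'
#' Partitions two called-interactor sets into exclusive and shared parts and
#' reports the percentage growth from A to B and the share of B that is
#' common with A.
#'
#' @param a,b character vectors of protein ids (interactomes A and B).
#' @return an \code{InteractomeComparison} list: \code{a_only},
#'   \code{b_only}, \code{shared}, sizes, \code{pct_increase}
#'   (\eqn{100 (|B|-|A|)/|A|}) and \code{pct_shared_of_b}
#'   (\eqn{100 |A \cap B| / |B|}).
#' @examples
#' compareInteractomes(letters[1:4], letters[3:8])
#' @export
compareInteractomes <- function(a, b) {
    a <- unique(as.character(a))
    b <- unique(as.character(b))
    if (!length(a)) stop("undefined percentage: interactome A is empty")
    shared <- intersect(a, b)
    res <- list(
        a_only = setdiff(a, b),
        b_only = setdiff(b, a),
        shared = shared,
        size_a = length(a),
        size_b = length(b),
        n_shared = length(shared),
        pct_increase = 100 * (length(b) - length(a)) / length(a),
        pct_shared_of_b = if (length(b)) 100 * length(shared) / length(b)
                          else NA_real_)
    class(res) <- "InteractomeComparison"
    res
}

#' @export
print.InteractomeComparison <- function(x, ...) {
    cat(sprintf(
        "InteractomeComparison: |A| = %d, |B| = %d, shared = %d\n",
        x$size_a, x$size_b, x$n_shared))
    cat(sprintf("  increase A -> B: %.1f%%; shared of B: %.1f%%\n",
                x$pct_increase, x$pct_shared_of_b))
    invisible(x)
}

#' Fraction of an interactome falling in a subset
#'
#' E.g. the share of called interactors annotated to a cellular compartment.
#' Subset ids outside the interactome are ignored with a warning.
#'
#' @param interactome character vector of called interactor ids (non-empty).
#' @param subsetIds character vector of ids defining the subset.
#' @return percentage \eqn{100 |subset \cap interactome| / |interactome|}.
#' @export
localizationFraction <- function(interactome, subsetIds) {
    interactome <- unique(as.character(interactome))
    subsetIds <- unique(as.character(subsetIds))
    if (!length(interactome)) stop("empty interactome")
    extra <- setdiff(subsetIds, interactome)
    if (length(extra))
        warning(length(extra), " subset id(s) not in the interactome ",
                "ignored: ", paste(utils::head(extra, 5), collapse = ", "),
                if (length(extra) > 5) ", ..." else "")
    100 * length(intersect(subsetIds, interactome)) / length(interactome)
}
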