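#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData colData<- rowData
NULL

GENOTYPE_LEVELS <- c("WT", "WT_TG2KO", "APP23", "APP23_TG2KO")
ASSAY_LEVELS <- c("IP", "TOTAL")

#' Protein quantification matrix with detection mask
#'
#' A \code{QuantMatrix} holds protein-level peak areas from SWATH-DIA (or any
#' label-free) quantification as a proteins-by-samples
#' \linkS4class{SummarizedExperiment} with two assays: \code{area} (positive
#' reals; 0 where not detected) and \code{detected} (logical mask).
#' Nondetection is explicit and is carried through every downstream stage;
#' no reader or transformation silently imputes.
#'
#' @slot .  inherits all slots from \code{SummarizedExperiment}.
#' @seealso [readQuantTable()], [zTransform()], [simulateIpExperiment()]
#' @export
setClass("QuantMatrix", contains = "SummarizedExperiment")

setValidity("QuantMatrix", function(object) {
    msg <- character()
    an <- assayNames(object)
    if (!all(c("area", "detected") %in% an))
        return("assays 'area' and 'detected' are required")
    area <- assay(object, "area")
    det <- assay(object, "detected")
    if (!is.numeric(area)) msg <- c(msg, "'area' assay must be numeric")
    if (!is.logical(det)) msg <- c(msg, "'detected' assay must be logical")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "protein ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (is.numeric(area) && is.logical(det)) {
        bad <- det & !is.na(area) & area <= 0
        if (any(bad))
            msg <- c(msg, "every detected value must be strictly positive")
        if (any(is.na(det)))
            msg <- c(msg, "'detected' mask must not contain NA")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a QuantMatrix
#'
#' @param area numeric matrix of peak areas (proteins in rows, samples in
#'   columns); values at nondetected positions are ignored and stored as 0.
#' @param detected logical matrix of the same dimension; defaults to
#'   \code{area > 0}, i.e. zeros mark nondetection.
#' @param sampleData optional \code{DataFrame}/\code{data.frame} of per-sample
#'   metadata (see [readSampleSheet()]), one row per column of \code{area}.
#' @return a \linkS4class{QuantMatrix}.
#' @examples
#' m <- matrix(c(10, 20, 0, 40), 2, 2,
#'             dimnames = list(c("APOE", "VINC"), c("s1", "s2")))
#' qm <- QuantMatrix(m)
#' detected(qm)
#' @export
QuantMatrix <- function(area, detected = area > 0, sampleData = NULL) {
    area <- as.matrix(area)
    detected <- as.matrix(detected)
    storage.mode(detected) <- "logical"
    dimnames(detected) <- dimnames(area)
    area[!detected] <- 0
    se_args <- list(assays = SimpleList(area = area, detected = detected))
    if (!is.null(sampleData)) se_args$colData <- DataFrame(sampleData)
    se <- do.call(SummarizedExperiment, se_args)
    new("QuantMatrix", se)
}

#' Z-score matrix
#'
#' Result of [zTransform()]: natural-log peak areas standardized against the
#' mean and population standard deviation of all detected entries jointly.
#' The \code{z} assay is \code{NA} where not detected; the log-population
#' mean and SD are kept in \code{metadata()} as \code{mu} and \code{sigma}.
#'
#' @export
setClass("ZMatrix", contains = "SummarizedExperiment")

setValidity("ZMatrix", function(object) {
    if (!all(c("z", "detected") %in% assayNames(object)))
        return("assays 'z' and 'detected' are required")
    TRUE
})

#' Simulation configuration for synthetic co-IP and total-proteome data
#'
#' Defaults encode the study design this package targets: four genotypes
#' (WT, WT_TG2KO, APP23, APP23_TG2KO) with 5 replicates each, interactome
#' sizes 159 (WT) and 238 (APP23) with 31 shared, a +2 population-SD
#' ln-scale enrichment for planted bait interactors, log-normal abundances
#' spanning roughly five orders of magnitude, and left-censoring of the
#' lowest 10\% of background-level signals.
#'
#' @slot nProteins number of proteins in the simulated universe.
#' @slot nInteractorsWt,nInteractorsApp23,nSharedInteractors planted
#'   interactor counts per phenotype and their overlap.
#' @slot ipEffect ln-scale enrichment of planted interactors in bait-positive
#'   IPs, in units of the population SD of ln abundance.
#' @slot nDeProteins planted disease-only differential proteins per direction
#'   pair (changed in both APP23 vs WT and APP23-KO vs WT-KO).
#' @slot deLog2fc planted log2 fold change for disease-only proteins.
#' @slot nLinkProteins planted knockout-dependent ("TG2-linked") proteins,
#'   half increased and half decreased.
#' @slot linkLog2fc planted log2 fold change magnitude for the linked
#'   signature.
#' @slot noiseSd ln-scale replicate (residual) SD.
#' @slot betweenProteinSd ln-scale SD of protein baselines.
#' @slot dropoutRate fraction of background-level signal falling below the
#'   detection floor (left-censoring).
#' @slot nReplicates animals per cohort.
#' @slot baselineLogMean ln-scale grand mean of peak areas.
#' @slot seed integer seed driving all randomness.
#' @seealso [SimConfig()], [simulateIpExperiment()], [simulateTotalProteomes()]
#' @export
setClass("SimConfig", representation(
    nProteins = "integer",
    nInteractorsWt = "integer",
    nInteractorsApp23 = "integer",
    nSharedInteractors = "integer",
    ipEffect = "numeric",
    nDeProteins = "integer",
    deLog2fc = "numeric",
    nLinkProteins = "integer",
    linkLog2fc = "numeric",
    noiseSd = "numeric",
    betweenProteinSd = "numeric",
    dropoutRate = "numeric",
    nReplicates = "integer",
    baselineLogMean = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    counts <- c(object@nProteins, object@nInteractorsWt,
                object@nInteractorsApp23, object@nSharedInteractors,
                object@nDeProteins, object@nLinkProteins)
    if (any(counts < 0)) msg <- c(msg, "counts must be non-negative")
    if (object@nSharedInteractors >
        min(object@nInteractorsWt, object@nInteractorsApp23))
        msg <- c(msg, "shared interactors must be <= min(wt, app23)")
    n_planted <- object@nInteractorsWt + object@nInteractorsApp23 -
        object@nSharedInteractors
    if (n_planted > object@nProteins)
        msg <- c(msg, "more planted interactors than proteins")
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
        msg <- c(msg, "dropoutRate must be in [0, 1)")
    if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
    if (object@betweenProteinSd < 0)
        msg <- c(msg, "betweenProteinSd must be >= 0")
    if (object@nReplicates < 2) msg <- c(msg, "nReplicates must be >= 2")
    if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param nProteins,nInteractorsWt,nInteractorsApp23,nSharedInteractors
#'   universe and planted-interactor sizes.
#' @param ipEffect planted IP enrichment in population-SD units (ln scale).
#' @param nDeProteins,deLog2fc disease-only differential planting.
#' @param nLinkProteins,linkLog2fc knockout-dependent signature planting.
#' @param noiseSd,betweenProteinSd,dropoutRate,nReplicates,baselineLogMean
#'   noise model; see the class documentation.
#' @param seed integer seed.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' SimConfig(nProteins = 500, seed = 7)
#' @export
SimConfig <- function(nProteins = 2000L,
                      nInteractorsWt = 159L,
                      nInteractorsApp23 = 238L,
                      nSharedInteractors = 31L,
                      ipEffect = 2.0,
                      nDeProteins = 60L,
                      deLog2fc = 1.0,
                      nLinkProteins = 100L,
                      linkLog2fc = 1.2,
                      noiseSd = 0.6,
                      betweenProteinSd = 3.0,
                      dropoutRate = 0.1,
                      nReplicates = 5L,
                      baselineLogMean = 18,
                      seed = 1L) {
    new("SimConfig",
        nProteins = as.integer(nProteins),
        nInteractorsWt = as.integer(nInteractorsWt),
        nInteractorsApp23 = as.integer(nInteractorsApp23),
        nSharedInteractors = as.integer(nSharedInteractors),
        ipEffect = as.numeric(ipEffect),
        nDeProteins = as.integer(nDeProteins),
        deLog2fc = as.numeric(deLog2fc),
        nLinkProteins = as.integer(nLinkProteins),
        linkLog2fc = as.numeric(linkLog2fc),
        noiseSd = as.numeric(noiseSd),
        betweenProteinSd = as.numeric(betweenProteinSd),
        dropoutRate = as.numeric(dropoutRate),
        nReplicates = as.integer(nReplicates),
        baselineLogMean = as.numeric(baselineLogMean),
        seed = as.integer(seed))
}

setMethod("show", "QuantMatrix", function(object) {
    det <- assay(object, "detected")
    cat(sprintf("QuantMatrix: %d proteins x %d samples (%.1f%% detected)\n",
                nrow(object), ncol(object), 100 * mean(det)))
    if (ncol(colData(object)) > 0)
        cat("  sample metadata:",
            paste(colnames(colData(object)), collapse = ", "), "\n")
})

setMethod("show", "ZMatrix", function(object) {
    cat(sprintf("ZMatrix: %d proteins x %d samples (mu = %.4g, sigma = %.4g)\n",
                nrow(object), ncol(object),
                metadata(object)$mu, metadata(object)$sigma))
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig\n")
    for (sl in slotNames(object))
        cat(sprintf("  %-20s %s\n", sl, slot(object, sl)))
})
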