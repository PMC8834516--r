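## Synthetic co-IP and total-proteome experiments with planted ground
## truth. Abundances are log-normal: protein baselines drawn once per
## simulation (between-protein spread), replicate values add ln-scale
## noise, matching the multiplicative error structure that motivates
## ln-based Z-normalization. Nondetection is left-censoring at a detection
## floor, not missing-at-random: the floor is the dropoutRate quantile of
## the null abundance distribution, so low-abundance signals are the ones
## that go missing, as in real IP background binding.

.protein_ids <- function(n) sprintf("PROT%05d", seq_len(n))

.sim_sheet <- function(genotypes, n_rep, assay) {
    df <- expand.grid(replicate = seq_len(n_rep), genotype = genotypes,
                      stringsAsFactors = FALSE)
    df$assay <- assay
    df$sample_id <- paste(df$genotype, assay, df$replicate, sep = "_")
    validateSampleSheet(df[, c("sample_id", "genotype", "assay",
                               "replicate")])
}

#' Simulate a knockout-controlled co-IP experiment
#'
#' Generates an IP peak-area matrix for the four genotypes (bait-positive
#' WT and APP23, plus their bait-knockout backgrounds) with
#' \code{nReplicates} animals each. Planted interactors are enriched by
#' \code{ipEffect} population-SD units (ln scale) in the bait-positive IPs
#' of their phenotype only; everything else behaves as background binding.
#' Values below the detection floor (the \code{dropoutRate} quantile of the
#' null abundance distribution) are censored to nondetected, across all
#' cohorts -- the detector does not know genotypes.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with \code{quant} (a \linkS4class{QuantMatrix} with the
#'   sample sheet attached), \code{sheet}, and \code{truth} (planted
#'   interactor ids per phenotype, the ln-scale detection floor, and the
#'   population SD used for the effect size).
#' @examples
#' sim <- simulateIpExperiment(SimConfig(nProteins = 300, seed = 7))
#' sim$quant
#' @export
simulateIpExperiment <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    n <- config@nProteins
    n_rep <- config@nReplicates
    sigma_pop <- sqrt(config@betweenProteinSd^2 + config@noiseSd^2)
    ids <- .protein_ids(n)
    sheet <- .sim_sheet(GENOTYPE_LEVELS, n_rep, "IP")
    .with_seed(config@seed, {
        set.seed(config@seed + 11L)   # sub-stream: baselines + planting
        baseline <- stats::rnorm(n, config@baselineLogMean,
                                 config@betweenProteinSd)
        n_pick <- config@nInteractorsWt + config@nInteractorsApp23 -
            config@nSharedInteractors
        picked <- sample.int(n, n_pick)
        shared <- picked[seq_len(config@nSharedInteractors)]
        wt_idx <- c(shared, picked[config@nSharedInteractors +
            seq_len(config@nInteractorsWt - config@nSharedInteractors)])
        app_idx <- c(shared,
                     picked[config@nInteractorsWt +
                            seq_len(n_pick - config@nInteractorsWt)])
        effect <- config@ipEffect * sigma_pop
        ln <- matrix(NA_real_, n, nrow(sheet),
                     dimnames = list(ids, sheet$sample_id))
        for (j in seq_len(nrow(sheet))) {
            set.seed(config@seed + 100L + j)   # sub-stream per sample
            ln[, j] <- baseline + stats::rnorm(n, 0, config@noiseSd)
        }
        pos_wt <- sheet$genotype == "WT"
        pos_app <- sheet$genotype == "APP23"
        ln[wt_idx, pos_wt] <- ln[wt_idx, pos_wt] + effect
        ln[app_idx, pos_app] <- ln[app_idx, pos_app] + effect
        floor_ln <- if (config@dropoutRate > 0)
            config@baselineLogMean +
                stats::qnorm(config@dropoutRate) * sigma_pop
        else -Inf
        det <- ln >= floor_ln
        area <- exp(ln)
        area[!det] <- 0
        quant <- QuantMatrix(area, det, sampleData = sheet)
        list(quant = quant,
             sheet = sheet,
             truth = list(interactors_wt = ids[sort(wt_idx)],
                          interactors_app23 = ids[sort(app_idx)],
                          interactors_shared = ids[sort(shared)],
                          floor_ln = floor_ln,
                          sigma_pop = sigma_pop))
    })
}

#' Simulate four total-proteome cohorts with planted differential structure
#'
#' Generates total-homogenate matrices for WT, WT-KO, APP23 and APP23-KO
#' with two kinds of planted signal, each half increased and half
#' decreased:
#' \itemize{
#'   \item disease-only proteins (\code{nDeProteins}, effect
#'     \code{deLog2fc}): shifted in both APP23 and APP23-KO -- they change
#'     with disease independently of TG2 and surface in the knockout
#'     contrast;
#'   \item TG2-linked proteins (\code{nLinkProteins}, effect
#'     \code{linkLog2fc}): shifted in APP23 only -- they appear in both
#'     primary contrasts with the same sign and in neither knockout-only
#'     contrast.
#' }
#' Total-proteome quantification is modeled without censoring: detection of
#' a brain homogenate proteome is essentially complete, unlike IP
#' background binding.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with \code{quant}, \code{sheet} and \code{truth}
#'   (\code{de_up}, \code{de_down}, \code{link_up}, \code{link_down} id
#'   vectors).
#' @export
simulateTotalProteomes <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    n <- config@nProteins
    n_rep <- config@nReplicates
    ids <- .protein_ids(n)
    sheet <- .sim_sheet(GENOTYPE_LEVELS, n_rep, "TOTAL")
    n_de <- config@nDeProteins
    n_link <- config@nLinkProteins
    if (n_de + n_link > n)
        stop("more planted proteins than the universe holds")
    .with_seed(config@seed, {
        set.seed(config@seed + 29L)   # sub-stream: baselines + planting
        baseline <- stats::rnorm(n, config@baselineLogMean,
                                 config@betweenProteinSd)
        picked <- sample.int(n, n_de + n_link)
        de_idx <- picked[seq_len(n_de)]
        link_idx <- picked[n_de + seq_len(n_link)]
        de_sign <- rep(c(1, -1), length.out = n_de)
        link_sign <- rep(c(1, -1), length.out = n_link)
        ln <- matrix(NA_real_, n, nrow(sheet),
                     dimnames = list(ids, sheet$sample_id))
        for (j in seq_len(nrow(sheet))) {
            set.seed(config@seed + 500L + j)   # sub-stream per sample
            ln[, j] <- baseline + stats::rnorm(n, 0, config@noiseSd)
        }
        diseased <- sheet$genotype %in% c("APP23", "APP23_TG2KO")
        app_only <- sheet$genotype == "APP23"
        ln[de_idx, diseased] <- ln[de_idx, diseased] +
            de_sign * config@deLog2fc * log(2)
        ln[link_idx, app_only] <- ln[link_idx, app_only] +
            link_sign * config@linkLog2fc * log(2)
        quant <- QuantMatrix(exp(ln), matrix(TRUE, n, nrow(sheet)),
                             sampleData = sheet)
        list(quant = quant,
             sheet = sheet,
             truth = list(de_up = ids[de_idx[de_sign > 0]],
                          de_down = ids[de_idx[de_sign < 0]],
                          link_up = ids[link_idx[link_sign > 0]],
                          link_down = ids[link_idx[link_sign < 0]]))
    })
}
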