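## End-to-end workflow wiring and bundled reference tables.

#' Bundled reference tables from the TG2 co-IP study of APP23 mouse brain
#'
#' The package ships, as plain TSV under \code{inst/extdata}, the published
#' result tables of the knockout-controlled TG2 co-immunoprecipitation
#' study of APP23 and wild-type mouse brain that this workflow implements:
#' interactor calls (id, name, z-test p-value per phenotype, phenotype
#' membership) for the membrane/extracellular and cell-matrix compartments,
#' and the four confidence-filtered differential-abundance tables (id,
#' name, log2FC, confidence). They are the canonical regression surface for
#' the set-algebra and classification stages: the underlying raw data
#' require proprietary upstream processing, the printed tables are the
#' reproducible interface.
#'
#' @param name one of \code{"interactors_membrane_extracellular"},
#'   \code{"interactors_cell_matrix"}, \code{"de_app23_vs_wt"},
#'   \code{"de_app23_vs_app23ko"}, \code{"de_app23ko_vs_wtko"},
#'   \code{"de_wt_vs_wtko"}.
#' @return a data.frame. Interactor tables have columns \code{id},
#'   \code{name}, \code{p_wt}, \code{p_app23}, \code{phenotype} (one of
#'   \code{WT}, \code{APP23}, \code{WT_APP23}); differential tables have
#'   \code{id}, \code{name}, \code{log2fc}, \code{confidence}.
#' @examples
#' head(referenceTable("de_app23_vs_wt"))
#' @export
referenceTable <- function(name = c("interactors_membrane_extracellular",
                                    "interactors_cell_matrix",
                                    "de_app23_vs_wt",
                                    "de_app23_vs_app23ko",
                                    "de_app23ko_vs_wtko",
                                    "de_wt_vs_wtko")) {
    name <- match.arg(name)
    path <- system.file("extdata", paste0(name, ".tsv"),
                        package = "DeltaZIP", mustWork = TRUE)
    utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                      stringsAsFactors = FALSE, encoding = "UTF-8")
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

.write_tsv <- function(df, path) {
    utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

#' Run the full knockout-controlled co-IP analysis workflow
#'
#' Executes the in-silico portion of the study design end to end:
#' interactor screens for both phenotypes (WT and APP23) against their
#' knockout backgrounds, interactome comparison, differential abundance on
#' the four genotype contrasts of the total proteomes, confidence
#' filtering, TG2-linked classification with interactor-overlap annotation,
#' and (optionally) annotation overrepresentation of the concordant
#' proteins. All tables are written to \code{outDir} together with a
#' \code{summary.json} (set sizes, percentages, label counts -- recomputed
#' from the emitted sets as an internal consistency check) and a plain-text
#' log recording package version, configuration and seed.
#'
#' @param ipMatrix IP \linkS4class{QuantMatrix} or path to one.
#' @param totalMatrix total-proteome \linkS4class{QuantMatrix} or path.
#' @param sampleSheet sample sheet (object or path) covering both assays.
#' @param annotationSets optional named list (or GMT path) for the
#'   enrichment stage.
#' @param outDir output directory, created if needed.
#' @param alpha interactor-call significance level.
#' @param confidenceThreshold differential-abundance confidence threshold.
#' @param nBoot bootstrap resamples per protein.
#' @param seed integer seed for every stochastic stage (mandatory).
#' @return invisibly, a list with all stage results and the summary.
#' @export
runPipeline <- function(ipMatrix, totalMatrix, sampleSheet,
                        annotationSets = NULL, outDir,
                        alpha = 0.05, confidenceThreshold = 0.545,
                        nBoot = 2000, seed) {
    if (missing(seed)) stop("seed is mandatory")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    log_path <- file.path(outDir, "run.log")
    logline <- function(...) {
        msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
        message(msg)
        cat(msg, "\n", file = log_path, append = TRUE)
    }
    logline("DeltaZIP ", as.character(utils::packageVersion("DeltaZIP")),
            " | alpha=", alpha, " confidence>=", confidenceThreshold,
            " nBoot=", nBoot, " seed=", seed)

    sheet <- .stage("sample sheet", {
        if (is.character(sampleSheet)) readSampleSheet(sampleSheet)
        else validateSampleSheet(as.data.frame(sampleSheet))
    })
    ip <- .stage("IP matrix", {
        m <- if (is.character(ipMatrix)) readQuantTable(ipMatrix)
             else ipMatrix
        attachSampleSheet(m, sheet[sheet$assay == "IP", ])
    })
    tot <- .stage("total matrix", {
        m <- if (is.character(totalMatrix)) readQuantTable(totalMatrix)
             else totalMatrix
        attachSampleSheet(m, sheet[sheet$assay == "TOTAL", ])
    })

    screens <- lapply(c(WT = "WT", APP23 = "APP23"), function(ph)
        .stage(paste0("interactor screen ", ph),
               suppressMessages(interactorScreen(ip, ph, alpha = alpha))))
    for (ph in names(screens))
        .write_tsv(screens[[ph]],
                   file.path(outDir, paste0("interactors_", ph, ".tsv")))
    called <- lapply(screens, function(s) s$protein_id[s$called])
    comp <- .stage("interactome comparison",
                   compareInteractomes(called$WT, called$APP23))
    logline("interactome: WT ", comp$size_a, ", APP23 ", comp$size_b,
            ", shared ", comp$n_shared)

    contrasts <- list(
        app_vs_wt = c("APP23", "WT"),
        app_vs_appko = c("APP23", "APP23_TG2KO"),
        appko_vs_wtko = c("APP23_TG2KO", "WT_TG2KO"),
        wt_vs_wtko = c("WT", "WT_TG2KO"))
    de <- lapply(seq_along(contrasts), function(i)
        .stage(paste0("differential abundance ",
                      paste(contrasts[[i]], collapse = " vs ")),
               suppressWarnings(diffExpr(tot, contrasts[[i]],
                                         nBoot = nBoot,
                                         seed = seed + i))))
    names(de) <- names(contrasts)
    filtered <- lapply(de, filterByConfidence,
                       threshold = confidenceThreshold)
    for (nm in names(filtered))
        .write_tsv(filtered[[nm]],
                   file.path(outDir, paste0("de_", nm, ".tsv")))

    labels <- .stage("TG2-linked classification",
        suppressMessages(classifyTg2Linked(
            filtered$app_vs_wt, filtered$app_vs_appko,
            filtered$appko_vs_wtko, filtered$wt_vs_wtko)))
    labels <- suppressMessages(
        annotateInteractorOverlap(labels, called$APP23))
    .write_tsv(labels, file.path(outDir, "tg2link_labels.tsv"))

    enrichment <- NULL
    if (!is.null(annotationSets)) {
        sets <- if (is.character(annotationSets))
            readAnnotationSets(annotationSets) else annotationSets
        target <- labels$protein_id[grepl("^concordant",
                                          labels$label)]
        if (length(target))
            enrichment <- .stage("enrichment",
                fisherOverrepresentation(target, proteinIds(tot), sets))
        if (!is.null(enrichment))
            .write_tsv(enrichment, file.path(outDir, "enrichment.tsv"))
    }

    label_counts <- table(labels$label)
    summary <- list(
        interactome = list(
            size_wt = comp$size_a, size_app23 = comp$size_b,
            n_shared = comp$n_shared,
            pct_increase = comp$pct_increase,
            pct_shared_of_app23 = comp$pct_shared_of_b),
        tg2link = as.list(setNames(as.integer(label_counts),
                                   names(label_counts))),
        parameters = list(alpha = alpha,
                          confidence_threshold = confidenceThreshold,
                          n_boot = nBoot, seed = seed))
    # internal consistency: percentages must be recomputable from the sets
    stopifnot(isTRUE(all.equal(
        summary$interactome$pct_increase,
        100 * (length(called$APP23) - length(called$WT)) /
            length(called$WT))))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    logline("labels: ",
            paste(names(label_counts), as.integer(label_counts),
                  sep = "=", collapse = ", "))
    invisible(list(screens = screens, comparison = comp,
                   diffexpr = de, filtered = filtered, labels = labels,
                   enrichment = enrichment, summary = summary))
}
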