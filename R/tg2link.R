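## Sign-consistency classification of the knockout-linked pathological
## proteome from four genotype contrasts.

TG2LINK_LABELS <- c("concordant_increased", "concordant_decreased",
                    "discordant", "ko_confounded", "not_tg2_linked")

.check_contrast_table <- function(df, what) {
    df <- as.data.frame(df)
    id_col <- if ("protein_id" %in% colnames(df)) "protein_id" else "id"
    if (!all(c(id_col, "log2fc") %in% colnames(df)))
        stop(what, " needs columns 'protein_id' (or 'id') and 'log2fc'")
    if (anyDuplicated(df[[id_col]]))
        stop("duplicated protein in ", what, ": ",
             df[[id_col]][duplicated(df[[id_col]])][1L])
    setNames(df$log2fc, df[[id_col]])
}

#' Classify proteins into the TG2-linked pathological proteome
#'
#' Cross-compares four confidence-filtered differential tables: the disease
#' contrast (APP23 vs WT), the TG2-dependence contrast (APP23 vs
#' APP23/TG2-knockout) and the two knockout-background contrasts
#' (APP23-KO vs WT-KO, WT vs WT-KO). A protein is part of the TG2-linked
#' pathological proteome when its disease change is sign-concordant with
#' its TG2 dependence \emph{and} it shows no change in either knockout
#' contrast -- the latter excludes changes that occur independently of TG2
#' expression. "No change" means absence from the confidence-filtered list.
#'
#' Labels, assigned in order:
#' \describe{
#'   \item{concordant_increased / concordant_decreased}{same-signed log2FC
#'     in both primary contrasts, absent from both knockout contrasts.}
#'   \item{ko_confounded}{present in either knockout-background contrast.}
#'   \item{discordant}{present in both primary contrasts with opposite
#'     signs; such sign conflicts are also reported via \code{message()}
#'     since they flag internally inconsistent evidence.}
#'   \item{not_tg2_linked}{everything else in the union.}
#' }
#'
#' @param appVsWt,appVsAppko,appkoVsWtko,wtVsWtko confidence-filtered
#'   tables (DataFrame/data.frame with \code{protein_id}/\code{id} and
#'   \code{log2fc}); the threshold is assumed to have been applied already
#'   (see [filterByConfidence()]).
#' @return a [S4Vectors::DataFrame] with one row per protein of the union:
#'   \code{protein_id}, \code{label}, and the four per-contrast log2FC
#'   evidence columns (NA where absent).
#' @examples
#' t_dis <- data.frame(protein_id = c("RAB1B", "GNAZ"), log2fc = c(1.03, 0.32))
#' t_dep <- data.frame(protein_id = c("RAB1B", "GNAZ"), log2fc = c(1.01, -0.37))
#' none <- data.frame(protein_id = character(), log2fc = numeric())
#' classifyTg2Linked(t_dis, t_dep, none, none)
#' @export
classifyTg2Linked <- function(appVsWt, appVsAppko, appkoVsWtko, wtVsWtko) {
    dis <- .check_contrast_table(appVsWt, "disease contrast (APP23 vs WT)")
    dep <- .check_contrast_table(appVsAppko,
                                 "TG2-dependence contrast (APP23 vs APP23-KO)")
    ko1 <- .check_contrast_table(appkoVsWtko,
                                 "knockout contrast (APP23-KO vs WT-KO)")
    ko2 <- .check_contrast_table(wtVsWtko, "knockout contrast (WT vs WT-KO)")
    ids <- unique(c(names(dis), names(dep), names(ko1), names(ko2)))
    lab <- character(length(ids))
    for (i in seq_along(ids)) {
        id <- ids[i]
        in_dis <- id %in% names(dis)
        in_dep <- id %in% names(dep)
        in_ko <- id %in% names(ko1) || id %in% names(ko2)
        lab[i] <- if (in_dis && in_dep && !in_ko &&
                      sign(dis[[id]]) == sign(dep[[id]]) &&
                      dis[[id]] != 0) {
            if (dis[[id]] > 0) "concordant_increased"
            else "concordant_decreased"
        } else if (in_ko) {
            "ko_confounded"
        } else if (in_dis && in_dep &&
                   sign(dis[[id]]) != sign(dep[[id]])) {
            "discordant"
        } else {
            "not_tg2_linked"
        }
    }
    disc <- ids[lab == "discordant"]
    if (length(disc))
        message("sign conflict between disease and TG2-dependence ",
                "contrasts for: ", paste(disc, collapse = ", "),
                " -- evidence is internally inconsistent; labeled discordant")
    DataFrame(protein_id = ids,
              label = factor(lab, levels = TG2LINK_LABELS),
              log2fc_app_vs_wt = unname(dis[ids]),
              log2fc_app_vs_appko = unname(dep[ids]),
              log2fc_appko_vs_wtko = unname(ko1[ids]),
              log2fc_wt_vs_wtko = unname(ko2[ids]))
}

#' Flag which classified proteins are also bait interactors
#'
#' @param labels result of [classifyTg2Linked()].
#' @param interactome character vector of called interactor ids (e.g. the
#'   \code{called} subset of an [interactorScreen()] result).
#' @return \code{labels} with a logical \code{is_tg2_interactor} column;
#'   the overlap count is reported in a message.
#' @export
annotateInteractorOverlap <- function(labels, interactome) {
    interactome <- unique(as.character(interactome))
    labels$is_tg2_interactor <- labels$protein_id %in% interactome
    message(sum(labels$is_tg2_interactor), " of ", nrow(labels),
            " classified protein(s) are also bait interactors")
    labels
}
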