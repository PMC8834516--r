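## Fisher-exact overrepresentation of a target set against a background
## universe, Bonferroni-corrected over the terms actually testable.

#' Annotation overrepresentation by Fisher's exact test
#'
#' For each annotation term, tests whether the target set contains more
#' term members than expected from the background universe, with the
#' one-sided (overrepresentation tail) Fisher exact test on the 2x2 table
#' (in-term/out-of-term x in-target/out-of-target). Term memberships are
#' intersected with the background first; terms left empty are excluded
#' both from testing and from the Bonferroni divisor -- untestable
#' hypotheses should not pay correction cost. The background defaults to
#' the quantified universe of the run rather than a whole genome; pass an
#' external background list to reproduce genome-wide testing.
#'
#' @param target character vector of protein ids; must be a subset of
#'   \code{background}.
#' @param background character vector: the universe.
#' @param sets named list of term member vectors ([readAnnotationSets()]).
#' @return a [S4Vectors::DataFrame] sorted by raw p, one row per testable
#'   term: \code{term_id}, \code{k} (targets in term), \code{K} (background
#'   in term), \code{n} (target size), \code{N} (background size),
#'   \code{fold_enrichment} = (k/n)/(K/N), \code{p_raw},
#'   \code{p_bonferroni} = min(1, p_raw * number of terms tested).
#' @examples
#' sets <- list(A = c("p1", "p2", "p3"), B = c("p4", "p5"))
#' fisherOverrepresentation(c("p1", "p2"), paste0("p", 1:10), sets)
#' @export
fisherOverrepresentation <- function(target, background, sets) {
    target <- unique(as.character(target))
    background <- unique(as.character(background))
    stray <- setdiff(target, background)
    if (length(stray))
        stop("target id(s) not in background: ",
             paste(utils::head(stray, 10), collapse = ", "),
             if (length(stray) > 10) ", ..." else "")
    if (!is.list(sets) || is.null(names(sets)))
        stop("sets must be a named list of member vectors")
    N <- length(background)
    n <- length(target)
    members <- lapply(sets, function(m) intersect(unique(m), background))
    testable <- lengths(members) > 0L
    members <- members[testable]
    n_tested <- length(members)
    if (!n_tested) stop("no term overlaps the background universe")
    rows <- lapply(names(members), function(tm) {
        K <- length(members[[tm]])
        k <- length(intersect(members[[tm]], target))
        tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), 2L, 2L)
        p <- stats::fisher.test(tab, alternative = "greater")$p.value
        DataFrame(term_id = tm, k = k, K = K, n = n, N = N,
                  fold_enrichment = (k / n) / (K / N),
                  p_raw = p)
    })
    out <- do.call(rbind, rows)
    out$p_bonferroni <- pmin(1, out$p_raw * n_tested)
    out[order(out$p_raw), ]
}
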