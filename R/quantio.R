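## Readers, writers and validation for quantification matrices, sample
## sheets and annotation sets. Delimiter is chosen by file extension:
## ".csv" is comma-separated, anything else tab-separated. UTF-8 throughout.

.sep_for <- function(path) {
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a protein quantification table
#'
#' Parses a delimited text file with protein identifiers in the first column
#' and one column per sample. Empty cells and literal zeros both mark
#' nondetection (SWATH exports use either convention); peak areas are
#' strictly positive when real. The orientation is fixed as
#' proteins-in-rows; a transposed file is a data error, never auto-fixed.
#'
#' @param path file path; \code{.csv} is read comma-separated, anything else
#'   tab-separated.
#' @return a \linkS4class{QuantMatrix} with the detection mask set.
#' @section Errors:
#' Duplicated protein ids, negative values, non-numeric cells and ragged
#' rows are hard errors naming the offending id or row.
#' @seealso [writeQuantTable()], [readSampleSheet()]
#' @export
readQuantTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- .sep_for(path)
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines)) | seq_along(lines) == 1L]
    if (length(lines) < 2L) stop("quantification table needs a header and at least one row")
    # field count by separator count: robust to trailing empty cells,
    # which strsplit() silently drops
    nf <- vapply(lines, function(l) {
        m <- gregexpr(sep, l, fixed = TRUE)[[1L]]
        if (m[1L] == -1L) 1L else length(m) + 1L
    }, 0L, USE.NAMES = FALSE)
    width <- nf[1L]
    ragged <- which(nf != width)
    if (length(ragged))
        stop("ragged row ", ragged[1L], ": ", nf[ragged[1L]],
             " fields where the header has ", width)
    fields <- strsplit(lines, sep, fixed = TRUE)
    fields <- lapply(fields, function(f) c(f, rep("", width - length(f))))
    header <- fields[[1L]]
    sample_ids <- trimws(header[-1L])
    if (anyDuplicated(sample_ids))
        stop("duplicated sample id: ",
             sample_ids[duplicated(sample_ids)][1L])
    body <- fields[-1L]
    ids <- trimws(vapply(body, `[`, "", 1L))
    if (anyDuplicated(ids))
        stop("duplicated protein id: ", ids[duplicated(ids)][1L])
    cells <- t(vapply(body, function(f) trimws(f[-1L]),
                      character(length(sample_ids))))
    if (length(sample_ids) == 1L) cells <- matrix(cells, ncol = 1L)
    vals <- suppressWarnings(matrix(as.numeric(cells), nrow = length(ids)))
    blank <- !nzchar(cells) | toupper(cells) %in% c("NA", "NAN")
    bad <- which(is.na(vals) & !blank)
    if (length(bad))
        stop("non-numeric value '", cells[bad[1L]], "' for protein ",
             ids[(bad[1L] - 1L) %% length(ids) + 1L])
    if (any(vals < 0, na.rm = TRUE)) {
        neg <- which(vals < 0)[1L]
        stop("negative peak area for protein ",
             ids[(neg - 1L) %% length(ids) + 1L])
    }
    vals[blank] <- 0
    dimnames(vals) <- list(ids, sample_ids)
    QuantMatrix(vals, detected = vals > 0)
}

#' Write a QuantMatrix to delimited text
#'
#' The inverse of [readQuantTable()]: nondetected cells are written as empty
#' strings and values with full \code{\%.17g} precision so that a
#' write-then-read round trip reproduces the matrix bit-identically.
#'
#' @param x a \linkS4class{QuantMatrix}.
#' @param path output path (\code{.csv} comma, otherwise tab).
#' @return \code{path}, invisibly.
#' @export
writeQuantTable <- function(x, path) {
    stopifnot(is(x, "QuantMatrix"))
    sep <- .sep_for(path)
    a <- areas(x)
    d <- detected(x)
    cells <- matrix(sprintf("%.17g", a), nrow = nrow(a))
    cells[!d] <- ""
    lines <- c(paste(c("protein_id", colnames(a)), collapse = sep),
               vapply(seq_len(nrow(a)), function(i)
                   paste(c(rownames(a)[i], cells[i, ]), collapse = sep), ""))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

#' Read and validate a sample sheet
#'
#' Expects columns \code{sample_id}, \code{genotype}, \code{assay},
#' \code{replicate}. Genotype must be one of \code{WT}, \code{WT_TG2KO},
#' \code{APP23}, \code{APP23_TG2KO}; assay one of \code{IP}, \code{TOTAL};
#' replicates positive integers. The (genotype, assay, replicate) triplet
#' must be unique -- each slot in the design names one animal's sample.
#'
#' @param path delimited text file (\code{.csv} comma, otherwise tab).
#' @return a validated [S4Vectors::DataFrame] keyed by \code{sample_id}.
#' @export
readSampleSheet <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.table(path, sep = .sep_for(path), header = TRUE,
                            stringsAsFactors = FALSE, encoding = "UTF-8")
    validateSampleSheet(df)
}

#' Validate a sample sheet already in memory
#'
#' @param df data.frame with columns \code{sample_id}, \code{genotype},
#'   \code{assay}, \code{replicate}.
#' @return a validated [S4Vectors::DataFrame].
#' @export
validateSampleSheet <- function(df) {
    df <- as.data.frame(df)
    need <- c("sample_id", "genotype", "assay", "replicate")
    missing_cols <- setdiff(need, colnames(df))
    if (length(missing_cols))
        stop("sample sheet lacks column(s): ",
             paste(missing_cols, collapse = ", "))
    bad_g <- setdiff(unique(df$genotype), GENOTYPE_LEVELS)
    if (length(bad_g))
        stop("unknown genotype '", bad_g[1L], "'; allowed: ",
             paste(GENOTYPE_LEVELS, collapse = ", "))
    bad_a <- setdiff(unique(df$assay), ASSAY_LEVELS)
    if (length(bad_a))
        stop("unknown assay '", bad_a[1L], "'; allowed: ",
             paste(ASSAY_LEVELS, collapse = ", "))
    rep_num <- suppressWarnings(as.integer(df$replicate))
    if (any(is.na(rep_num)) || any(rep_num < 1L))
        stop("replicate must be a positive integer")
    df$replicate <- rep_num
    if (anyDuplicated(df$sample_id))
        stop("duplicated sample_id: ",
             df$sample_id[duplicated(df$sample_id)][1L])
    key <- paste(df$genotype, df$assay, df$replicate)
    if (anyDuplicated(key))
        stop("duplicated (genotype, assay, replicate) triplet: (",
             paste(strsplit(key[duplicated(key)][1L], " ")[[1L]],
                   collapse = ", "), ")")
    out <- DataFrame(df[need])
    rownames(out) <- df$sample_id
    out
}

#' Write a sample sheet
#'
#' @param sheet a sample sheet as returned by [readSampleSheet()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSampleSheet <- function(sheet, path) {
    utils::write.table(as.data.frame(sheet), path, sep = .sep_for(path),
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Attach sample metadata to a QuantMatrix
#'
#' Every sample id of the matrix must appear exactly once in the sheet;
#' rows are reordered to the matrix column order and stored as
#' \code{colData}.
#'
#' @param x a \linkS4class{QuantMatrix}.
#' @param sheet a validated sample sheet.
#' @return \code{x} with \code{colData} set.
#' @export
attachSampleSheet <- function(x, sheet) {
    sheet <- validateSampleSheet(as.data.frame(sheet))
    absent <- setdiff(sampleIds(x), sheet$sample_id)
    if (length(absent))
        stop("sample(s) missing from sheet: ",
             paste(absent, collapse = ", "))
    sheet <- sheet[match(sampleIds(x), sheet$sample_id), , drop = FALSE]
    colData(x) <- sheet
    x
}

#' Read annotation sets (GMT or two-column long format)
#'
#' Both dialects are accepted and auto-detected by column count: a GMT line
#' is \code{term <tab> description <tab> member...}; long format has exactly
#' two columns, \code{term_id <tab> protein}. Members are deduplicated; terms
#' without members are skipped with a warning. GMT parsing is delegated to
#' \code{fgsea::gmtPathways}.
#'
#' @param path annotation file.
#' @return named list of character member vectors; term descriptions (GMT
#'   only) in \code{attr(., "termNames")}.
#' @export
readAnnotationSets <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty annotation file: ", path)
    nfield <- vapply(strsplit(lines, "\t", fixed = TRUE), length, 0L)
    if (max(nfield) <= 2L) {                      # long format
        fields <- strsplit(lines, "\t", fixed = TRUE)
        first <- fields[[1L]]
        if (identical(tolower(first), c("term_id", "protein")))
            fields <- fields[-1L]
        short <- vapply(fields, length, 0L) < 2L
        if (any(short)) {
            warning(sum(short), " line(s) without a member skipped")
            fields <- fields[!short]
        }
        term <- vapply(fields, `[`, "", 1L)
        member <- vapply(fields, `[`, "", 2L)
        sets <- lapply(split(member, term), unique)
        sets <- sets[unique(term)]                # keep file order
    } else {                                      # GMT
        sets <- lapply(fgsea::gmtPathways(path), unique)
        descr <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 2L)
        names(descr) <- vapply(strsplit(lines, "\t", fixed = TRUE),
                               `[`, "", 1L)
        attr(sets, "termNames") <- descr[names(sets)]
    }
    empty <- lengths(sets) == 0L | !nzchar(names(sets))
    if (any(empty)) {
        warning("skipping ", sum(empty), " empty/unnamed term(s)")
        tn <- attr(sets, "termNames")
        sets <- sets[!empty]
        if (!is.null(tn)) attr(sets, "termNames") <- tn[!empty]
    }
    sets
}

#' Write annotation sets in GMT format
#'
#' @param sets named list of member vectors ([readAnnotationSets()]).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationSets <- function(sets, path) {
    descr <- attr(sets, "termNames")
    if (is.null(descr)) descr <- setNames(rep("na", length(sets)), names(sets))
    lines <- vapply(names(sets), function(tm)
        paste(c(tm, descr[[tm]], sets[[tm]]), collapse = "\t"), "")
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}
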