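# Shared helpers: small builders for matrices and sheets, all in code.

random_quant <- function(n_prot = 10, n_samp = 4, seed = 1,
                         dropout = 0) {
    set.seed(seed)
    a <- matrix(exp(rnorm(n_prot * n_samp, 12, 2)), n_prot, n_samp,
                dimnames = list(sprintf("P%03d", seq_len(n_prot)),
                                sprintf("S%02d", seq_len(n_samp))))
    d <- matrix(runif(n_prot * n_samp) >= dropout, n_prot, n_samp)
    QuantMatrix(a, d)
}

four_cohort_sheet <- function(n_rep = 5, assay = "IP") {
    g <- c("WT", "WT_TG2KO", "APP23", "APP23_TG2KO")
    data.frame(
        sample_id = paste(rep(g, each = n_rep), assay,
                          rep(seq_len(n_rep), 4), sep = "_"),
        genotype = rep(g, each = n_rep),
        assay = assay,
        replicate = rep(seq_len(n_rep), 4))
}

# an IP pair (positive + background cohort) with fully detected values
pair_quant <- function(pos, bg, phenotype = "WT") {
    stopifnot(ncol(pos) == ncol(bg), nrow(pos) == nrow(bg))
    n_rep <- ncol(pos)
    bg_geno <- if (phenotype == "WT") "WT_TG2KO" else "APP23_TG2KO"
    a <- cbind(pos, bg)
    colnames(a) <- c(paste0("pos", seq_len(n_rep)),
                     paste0("bg", seq_len(n_rep)))
    rownames(a) <- if (is.null(rownames(pos)))
        sprintf("P%02d", seq_len(nrow(pos))) else rownames(pos)
    sheet <- data.frame(
        sample_id = colnames(a),
        genotype = rep(c(phenotype, bg_geno), each = n_rep),
        assay = "IP",
        replicate = rep(seq_len(n_rep), 2))
    attachSampleSheet(QuantMatrix(a), sheet)
}
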