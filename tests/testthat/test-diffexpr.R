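test_that("log2 fold change is the log-ratio of cohort means", {
    expect_equal(log2FoldChange(c(2, 2), c(2, 2)), 0)
    expect_equal(log2FoldChange(1, 4), -2)
    # mean ratio 2.014 -> ~1.01, the scale of a typical reported change
    expect_equal(log2FoldChange(c(2.014, 2.014), c(1, 1)), 1.01,
                 tolerance = 0.005)
    expect_warning(fc <- log2FoldChange(numeric(), c(1, 2)), "zero detected")
    expect_true(is.na(fc))
})

test_that("confidence is 1 for widely separated cohorts, 0.5 at zero fc", {
    a <- c(100, 101, 102, 103, 104)
    b <- a / 1000
    expect_equal(confidenceScore(a, b, nBoot = 200, seed = 1), 1)
    expect_equal(confidenceScore(c(2, 2), c(2, 2), nBoot = 100, seed = 1),
                 0.5)
})

test_that("confidence contract: seed required, nBoot >= 1, n >= 2", {
    expect_error(confidenceScore(1:3, 1:3, nBoot = 100), "seed")
    expect_error(confidenceScore(1:3, 1:3, nBoot = 0, seed = 1), "nBoot")
    expect_equal(confidenceScore(5, c(1, 2), nBoot = 100, seed = 1), 0)
})

# exhaustive enumeration of all resample combinations at n = 2: the exact
# expectation the bootstrap estimates
exact_confidence_n2 <- function(a, b) {
    point <- log2(mean(a) / mean(b))
    if (point == 0) return(0.5)
    hits <- 0; total <- 0
    for (i1 in 1:2) for (i2 in 1:2) for (j1 in 1:2) for (j2 in 1:2) {
        fc <- log2(mean(a[c(i1, i2)]) / mean(b[c(j1, j2)]))
        hits <- hits + (sign(fc) == sign(point))
        total <- total + 1
    }
    hits / total
}

test_that("bootstrap agrees with the exhaustive n = 2 oracle", {
    cases <- list(list(a = c(3, 9), b = c(2, 4)),
                  list(a = c(10, 2), b = c(3, 3.5)),
                  list(a = c(1, 1.1), b = c(1.05, 1.06)))
    for (cs in cases) {
        exact <- exact_confidence_n2(cs$a, cs$b)
        boot <- confidenceScore(cs$a, cs$b, nBoot = 4000, seed = 7)
        se <- sqrt(max(exact * (1 - exact), 0.25 / 4000) / 4000)
        expect_lt(abs(boot - exact), max(3 * se, 0.02))
    }
})

test_that("confidence is exchange-symmetric and monotone in the effect", {
    # exchange symmetry is exact for the enumerated expectation
    a <- c(3, 9); b <- c(2, 4)
    expect_equal(exact_confidence_n2(a, b), exact_confidence_n2(b, a))
    # and holds for the bootstrap up to Monte Carlo error
    set.seed(11)
    x <- exp(rnorm(5, 2, 0.3)); y <- exp(rnorm(5, 1.4, 0.3))
    expect_lt(abs(confidenceScore(x, y, nBoot = 4000, seed = 3) -
                  confidenceScore(y, x, nBoot = 4000, seed = 13)), 0.03)
    # monotone: larger true separation, at least as much confidence
    set.seed(4)
    base <- exp(rnorm(5, 0, 0.4))
    confs <- vapply(c(0, 0.5, 1, 2), function(shift)
        confidenceScore(base * 2^shift, base, nBoot = 2000, seed = 5), 0)
    expect_true(all(diff(confs) >= -0.02))
    expect_lt(confs[1], confs[4])
})

test_that("same-distribution cohorts score well below separated ones", {
    set.seed(19)
    null_conf <- replicate(20, {
        a <- exp(rnorm(5, 10, 0.6)); b <- exp(rnorm(5, 10, 0.6))
        confidenceScore(a, b, nBoot = 400, seed = 2)
    })
    sep_conf <- replicate(20, {
        a <- exp(rnorm(5, 12, 0.6)); b <- exp(rnorm(5, 10, 0.6))
        confidenceScore(a, b, nBoot = 400, seed = 2)
    })
    expect_lt(mean(null_conf), mean(sep_conf))
    expect_gt(mean(sep_conf), 0.95)
})

test_that("confidence filter keeps >= threshold and sorts by log2fc", {
    rec <- data.frame(protein_id = c("a", "b", "c", "d"),
                      log2fc = c(0.5, 2, -1, 1),
                      confidence = c(0.55, 0.54, 0.9, 0.545))
    out <- filterByConfidence(rec)
    expect_equal(out$protein_id, c("d", "a", "c"))   # 0.54 dropped
    expect_true(all(diff(out$log2fc) <= 0))
    empty <- filterByConfidence(rec[0, ])
    expect_equal(nrow(empty), 0L)
})

test_that("diffExpr computes per-protein records for a contrast", {
    sim <- simulateTotalProteomes(SimConfig(nProteins = 80,
                                            nInteractorsWt = 0,
                                            nInteractorsApp23 = 0,
                                            nSharedInteractors = 0,
                                            nDeProteins = 10,
                                            nLinkProteins = 10, seed = 2))
    de <- diffExpr(sim$quant, c("APP23", "WT"), nBoot = 200, seed = 1)
    expect_equal(nrow(de), 80L)
    expect_equal(unique(de$contrast), "APP23_vs_WT")
    expect_true(all(de$confidence >= 0 & de$confidence <= 1))
    expect_true(all(is.finite(de$log2fc)))
    expect_equal(de$n_a, rep(5L, 80))
    # same seed reproduces; different seed wiggles confidence only
    de2 <- diffExpr(sim$quant, c("APP23", "WT"), nBoot = 200, seed = 1)
    expect_identical(as.data.frame(de), as.data.frame(de2))
    expect_error(diffExpr(sim$quant, c("APP23", "WT"), nBoot = 200),
                 "seed")
})

test_that("proteins undetected in a whole cohort are dropped with warning", {
    sheet <- four_cohort_sheet(2, assay = "TOTAL")
    set.seed(6)
    a <- matrix(exp(rnorm(3 * 8, 8)), 3, 8,
                dimnames = list(c("p1", "p2", "p3"), sheet$sample_id))
    d <- a > 0
    d["p2", sheet$genotype == "WT"] <- FALSE
    qm <- attachSampleSheet(QuantMatrix(a, d), sheet)
    expect_warning(de <- diffExpr(qm, c("APP23", "WT"), nBoot = 50,
                                  seed = 1), "dropped")
    expect_false("p2" %in% de$protein_id)
})
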