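test_that("z-transform standardizes the joint detected population", {
    qm <- QuantMatrix(matrix(c(exp(1), exp(-1)), 1, 2,
                             dimnames = list("p", c("a", "b"))))
    expect_equal(unname(zValues(zTransform(qm))), matrix(c(1, -1), 1))

    expect_error(zTransform(QuantMatrix(
        matrix(5, 2, 2, dimnames = list(c("p1", "p2"), c("a", "b"))))),
        "degenerate population")
})

test_that("z-transform matches an independent two-pass oracle", {
    qm <- random_quant(10, 4, seed = 9)
    z <- zValues(zTransform(qm))
    # hand-rolled two-pass mean / population SD on the log values
    lv <- c()
    for (i in seq_len(nrow(qm))) for (j in seq_len(ncol(qm)))
        lv <- c(lv, log(areas(qm)[i, j]))
    mu <- sum(lv) / length(lv)
    ss <- 0
    for (v in lv) ss <- ss + (v - mu)^2
    sigma <- sqrt(ss / length(lv))
    expected <- (log(areas(qm)) - mu) / sigma
    expect_equal(z, expected, tolerance = 1e-12)
})

test_that("z population invariant holds across random inputs", {
    for (s in 1:8) {
        qm <- random_quant(30, 6, seed = s, dropout = s %% 3 / 10)
        z <- zTransform(qm)
        v <- zValues(z)[detected(z)]
        expect_lt(abs(mean(v)), 1e-9)
        expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-9)
    }
})

test_that("delta-Z is zero for identical cohorts and antisymmetric", {
    set.seed(21)
    pos <- matrix(exp(rnorm(6, 10)), 3, 2)
    qm <- pair_quant(pos, pos)
    dz <- deltaZ(zTransform(qm), "WT")
    expect_equal(dz$delta_z_mean, rep(0, 3))
    expect_true(all(dz$detected_in_all))

    bg <- matrix(exp(rnorm(6, 9)), 3, 2)
    qm2 <- pair_quant(pos, bg)
    qm3 <- pair_quant(bg, pos)   # cohorts swapped
    expect_equal(deltaZ(zTransform(qm2), "WT")$delta_z_mean,
                 -deltaZ(zTransform(qm3), "WT")$delta_z_mean)
})

test_that("delta-Z matches a hand computation on a 2x2 toy", {
    pos <- matrix(c(4, 6, 10, 14), 2, 2, byrow = TRUE)
    bg <- matrix(c(1, 2, 3, 5), 2, 2, byrow = TRUE)
    qm <- pair_quant(pos, bg, "APP23")
    dz <- deltaZ(zTransform(qm), "APP23")
    lv <- log(c(pos, bg))
    mu <- mean(lv)
    sigma <- sqrt(mean((lv - mu)^2))
    zp <- (log(pos) - mu) / sigma
    zb <- (log(bg) - mu) / sigma
    expect_equal(dz$delta_z_mean, rowMeans(zp) - rowMeans(zb),
                 tolerance = 1e-12)
})

test_that("unequal cohorts and absent phenotypes are errors", {
    set.seed(3)
    pos <- matrix(exp(rnorm(6, 10)), 3, 2)
    qm <- pair_quant(pos, pos)
    expect_error(deltaZ(zTransform(qm), "APP23"), "no IP samples")
    qm_uneq <- qm[, -1]
    expect_error(deltaZ(zTransform(qm_uneq), "WT"), "unequal cohort")
})

test_that("interactor calls follow the normal tail and detection filter", {
    dz <- S4Vectors::DataFrame(
        protein_id = c("null", "boundary", "strong", "gappy"),
        phenotype = "WT",
        delta_z_mean = c(0, qnorm(0.95), 4, 4),
        detected_in_all = c(TRUE, TRUE, TRUE, FALSE),
        n_replicates = 5L)
    calls <- callInteractors(dz)
    calls <- calls[match(dz$protein_id, calls$protein_id), ]
    expect_equal(calls$p_value, 1 - pnorm(dz$delta_z_mean),
                 tolerance = 1e-12)
    expect_equal(calls$p_value[1], 0.5)
    expect_false(calls$called[1])
    expect_equal(calls$p_value[2], 0.05, tolerance = 1e-6)
    # a protein with tiny p but a missing bait-positive replicate: never
    expect_true(calls$p_value[4] < 0.001)
    expect_false(calls$called[4])
})

test_that("strict boundary handling excludes p equal to alpha", {
    dz <- S4Vectors::DataFrame(protein_id = "p", phenotype = "WT",
                               delta_z_mean = 1.2,
                               detected_in_all = TRUE, n_replicates = 5L)
    p0 <- callInteractors(dz)$p_value
    expect_true(callInteractors(dz, alpha = p0)$called)
    expect_false(callInteractors(dz, alpha = p0, strict = TRUE)$called)
})

test_that("p is monotone decreasing in the delta-Z statistic", {
    dz <- S4Vectors::DataFrame(protein_id = sprintf("p%02d", 1:20),
                               phenotype = "WT",
                               delta_z_mean = seq(-2, 3, length.out = 20),
                               detected_in_all = TRUE, n_replicates = 5L)
    calls <- callInteractors(dz)
    ord <- match(dz$protein_id, calls$protein_id)
    expect_true(all(diff(calls$p_value[ord]) < 0))
})

test_that("interactome comparison reproduces the published set algebra", {
    a <- sprintf("W%03d", 1:159)
    b <- c(a[1:31], sprintf("A%03d", 1:207))
    comp <- compareInteractomes(a, b)
    expect_equal(comp$size_a, 159L)
    expect_equal(comp$size_b, 238L)
    expect_equal(comp$n_shared, 31L)
    expect_equal(round(comp$pct_increase), 50)
    expect_equal(comp$pct_shared_of_b, 100 * 31 / 238, tolerance = 1e-12)
    expect_equal(round(comp$pct_shared_of_b), 13)
    # the three parts partition the union
    expect_equal(length(comp$a_only) + length(comp$b_only) +
                     length(comp$shared), length(union(a, b)))
    expect_equal(length(comp$a_only) + length(comp$shared), length(a))
})

test_that("interactome comparison degenerate and edge cases", {
    expect_error(compareInteractomes(character(), "x"), "empty")
    same <- compareInteractomes(letters[1:4], letters[1:4])
    expect_equal(same$pct_increase, 0)
    expect_equal(same$pct_shared_of_b, 100)
    disj <- compareInteractomes(letters[1:3], LETTERS[1:6])
    expect_equal(disj$pct_increase, 100)
    expect_equal(disj$pct_shared_of_b, 0)
})

test_that("localization fractions behave as percentages of the set", {
    expect_equal(localizationFraction(letters[1:4], letters[1:4]), 100)
    expect_equal(localizationFraction(letters[1:10], letters[1:3]), 30)
    expect_warning(
        fr <- localizationFraction(letters[1:10], c("a", "zz")),
        "not in the interactome")
    expect_equal(fr, 10)
    expect_error(localizationFraction(character(), "a"), "empty")
})

test_that("background-floor imputation fills only background cells", {
    set.seed(8)
    a <- matrix(exp(rnorm(12, 10)), 3, 4)
    d <- matrix(TRUE, 3, 4)
    d[1, 3] <- FALSE   # background nondetection
    d[2, 1] <- FALSE   # bait-positive nondetection
    colnames(a) <- c("pos1", "pos2", "bg1", "bg2")
    rownames(a) <- c("p1", "p2", "p3")
    sheet <- data.frame(sample_id = colnames(a),
                        genotype = rep(c("WT", "WT_TG2KO"), each = 2),
                        assay = "IP", replicate = rep(1:2, 2))
    qm <- attachSampleSheet(QuantMatrix(a, d), sheet)
    expect_message(imp <- imputeBackgroundFloor(qm, "WT"), "imputed 1")
    expect_true(detected(imp)[1, 3])
    expect_equal(areas(imp)[1, 3], min(areas(qm)[detected(qm)]))
    expect_false(detected(imp)[2, 1])   # positive cohort left untouched
})
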