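test_that("simulation is deterministic given the seed", {
    cfg <- SimConfig(nProteins = 150, nInteractorsWt = 12,
                     nInteractorsApp23 = 18, nSharedInteractors = 5,
                     nDeProteins = 10, nLinkProteins = 10, seed = 7)
    s1 <- simulateIpExperiment(cfg)
    s2 <- simulateIpExperiment(cfg)
    expect_identical(areas(s1$quant), areas(s2$quant))
    expect_identical(s1$truth, s2$truth)
    t1 <- simulateTotalProteomes(cfg)
    t2 <- simulateTotalProteomes(cfg)
    expect_identical(areas(t1$quant), areas(t2$quant))
    # and a different seed changes the data
    s3 <- simulateIpExperiment(SimConfig(nProteins = 150,
                                         nInteractorsWt = 12,
                                         nInteractorsApp23 = 18,
                                         nSharedInteractors = 5,
                                         nDeProteins = 10,
                                         nLinkProteins = 10, seed = 8))
    expect_false(identical(areas(s1$quant), areas(s3$quant)))
})

test_that("generated matrices satisfy the container invariants", {
    sim <- simulateIpExperiment(SimConfig(nProteins = 200, seed = 3,
                                          nInteractorsWt = 20,
                                          nInteractorsApp23 = 30,
                                          nSharedInteractors = 5))
    expect_true(validObject(sim$quant))
    expect_true(all(areas(sim$quant)[detected(sim$quant)] > 0))
    expect_true(all(areas(sim$quant)[!detected(sim$quant)] == 0))
    expect_equal(nrow(sim$sheet), 20L)
    expect_equal(length(sim$truth$interactors_wt), 20L)
    expect_equal(length(sim$truth$interactors_app23), 30L)
    expect_equal(length(sim$truth$interactors_shared), 5L)
    expect_true(all(sim$truth$interactors_shared %in%
                    sim$truth$interactors_wt))
})

test_that("config validation rejects impossible designs", {
    expect_error(SimConfig(nProteins = 10, nInteractorsWt = 20,
                           nInteractorsApp23 = 0,
                           nSharedInteractors = 0),
                 "more planted interactors")
    expect_error(SimConfig(nSharedInteractors = 200), "shared")
    expect_error(SimConfig(dropoutRate = 1.2), "dropoutRate")
    expect_error(SimConfig(nReplicates = 1), "nReplicates")
})

test_that("a null experiment yields no planted separation", {
    # ipEffect = 0: planted ids are indistinguishable from the rest
    cfg <- SimConfig(nProteins = 600, nInteractorsWt = 50,
                     nInteractorsApp23 = 50, nSharedInteractors = 20,
                     ipEffect = 0, dropoutRate = 0, seed = 5)
    sim <- simulateIpExperiment(cfg)
    calls <- suppressMessages(interactorScreen(sim$quant, "WT"))
    planted <- calls$p_value[calls$protein_id %in%
                             sim$truth$interactors_wt]
    others <- calls$p_value[!calls$protein_id %in%
                            sim$truth$interactors_wt]
    expect_gt(stats::ks.test(planted, others)$p.value, 0.01)
})

test_that("a huge effect without dropout is called completely", {
    cfg <- SimConfig(nProteins = 400, nInteractorsWt = 30,
                     nInteractorsApp23 = 30, nSharedInteractors = 10,
                     ipEffect = 5, dropoutRate = 0, seed = 9)
    sim <- simulateIpExperiment(cfg)
    for (ph in c("WT", "APP23")) {
        calls <- suppressMessages(interactorScreen(sim$quant, ph))
        truth <- sim$truth[[paste0("interactors_", tolower(ph))]]
        expect_true(all(truth %in% calls$protein_id[calls$called]))
    }
})

test_that("planted fold changes are estimated without material bias", {
    sim <- simulateTotalProteomes(SimConfig(nProteins = 500,
                                            nDeProteins = 60,
                                            nLinkProteins = 0, seed = 11))
    de <- diffExpr(sim$quant, c("APP23", "WT"), nBoot = 100, seed = 1)
    est <- setNames(de$log2fc, de$protein_id)
    expect_lt(abs(median(est[sim$truth$de_up]) - 1.0), 0.15)
    expect_lt(abs(median(est[sim$truth$de_down]) + 1.0), 0.15)
})

test_that("a null total-proteome run yields only rare concordant labels", {
    # With the sign-consistency confidence, an unchanged protein still
    # passes the 0.545 filter with substantial probability, so a handful
    # of spurious concordant labels is expected by construction; they
    # must remain rare relative to the universe.
    cfg <- SimConfig(nProteins = 400, nDeProteins = 0, nLinkProteins = 0,
                     seed = 17)
    sim <- simulateTotalProteomes(cfg)
    contrasts <- list(c("APP23", "WT"), c("APP23", "APP23_TG2KO"),
                      c("APP23_TG2KO", "WT_TG2KO"), c("WT", "WT_TG2KO"))
    filt <- lapply(seq_along(contrasts), function(i) filterByConfidence(
        diffExpr(sim$quant, contrasts[[i]], nBoot = 200, seed = 100 + i)))
    lab <- suppressMessages(
        classifyTg2Linked(filt[[1]], filt[[2]], filt[[3]], filt[[4]]))
    frac <- mean(grepl("^concordant", lab$label))
    expect_lt(frac, 0.02)
})
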