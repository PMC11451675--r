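test_that("null effects are calibrated and the generating OR is recovered", {
    set.seed(71)
    null_ <- t(replicate(300, {
        r <- simulateSingleVariant(2000, 2000, 0.3, 1.0)
        c(r$beta, r$se)
    }))
    ## mean beta within 3 standard errors of 0
    expect_lt(abs(mean(null_[, 1])),
              3 * sd(null_[, 1]) / sqrt(nrow(null_)))

    set.seed(72)
    ors <- replicate(200, exp(simulateSingleVariant(20000, 20000,
                                                    0.3, 1.3)$beta))
    expect_equal(mean(ors), 1.3, tolerance = 0.01)
})

test_that("flipped emission is undone exactly by harmonization", {
    set.seed(73)
    rec <- simulateSingleVariant(5000, 5000, 0.25, 1.8,
                                 protectiveFraction = 1)
    expect_lt(rec$beta, 0)
    expect_identical(rec$effect_allele, "G")
    h <- harmonizeVariants(rec)
    expect_true(h$flipped)
    expect_gte(h$odds_ratio, 1)
    expect_identical(h$raf, 1 - rec$eaf)
    expect_identical(h$risk_allele, "A")
})

test_that("locus blocks reproduce the configured AR(1) LD and signal strength", {
    set.seed(74)
    blk <- simulateLocusBlock(20, 10, 0.3, 1.3, 0.7, 4200, 4200)
    R <- ldMatrix(blk)
    expect_identical(dim(R), c(20L, 20L))
    expect_equal(R, t(R))
    expect_equal(unname(diag(R)), rep(1, 20))
    expect_true(all(eigen(R, only.values = TRUE)$values > 0))
    expect_equal(R[1, 2], 0.7)
    expect_equal(R[1, 20], 0.7^19)

    ## with no LD, non-causal variants have mean z 0; causal mean z ~ lambda
    lambda <- expectedWaldZ(4200, 4200, 0.3, 1.3)$z
    set.seed(75)
    zs <- replicate(500, {
        v <- variantTable(simulateLocusBlock(5, 3, 0.3, 1.3, 0, 4200, 4200))
        ifelse(v$flipped, -1, 1) * v$beta / v$se
    })
    mz <- rowMeans(zs)
    semc <- apply(zs, 1, sd) / sqrt(ncol(zs))
    expect_true(all(abs(mz[-3]) < 3 * semc[-3]))
    expect_lt(abs(mz[3] - lambda), 3 * semc[3])

    expect_error(simulateLocusBlock(5, 3, 0.3, 1.3, 1.0, 100, 100), "ldRho")
    expect_error(simulateLocusBlock(5, 9, 0.3, 1.3, 0.5, 100, 100),
                 "causalIndex")
})

test_that("whole studies are seed-deterministic with correct ground truth", {
    cfg <- simulationConfig(99,
        ancestries = list(list(label = "EUR", n_cases = 1000,
                               n_controls = 1000)),
        loci = list(list(label = "L1", n_variants = 1, causal_index = 1,
                         ld_rho = 0, true_or = 1.3, true_raf = 0.3),
                    list(label = "L2", n_variants = 4, causal_index = 2,
                         ld_rho = 0.5, true_or = 0.7, true_raf = 0.6)))
    d1 <- tempfile(); d2 <- tempfile()
    simulateStudy(cfg, d1)
    simulateStudy(cfg, d2)
    for (f in list.files(d1))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))

    st <- simulateStudy(cfg)
    expect_equal(st$truth$true_par[st$truth$locus == "L1"], 0.09 / 1.09,
                 tolerance = 1e-12)
    ## protective generating effect: truth PAR uses the risk orientation
    expect_equal(st$truth$true_par[st$truth$locus == "L2"],
                 computePAR(0.4, 1 / 0.7), tolerance = 1e-12)
    expect_identical(nrow(variantTable(st$strata$EUR)), 5L)
    expect_true(validObject(st$strata$EUR))

    empty <- simulateStudy(simulationConfig(1,
        ancestries = list(list(label = "EUR", n_cases = 10,
                               n_controls = 10)),
        loci = list()))
    expect_identical(nrow(empty$truth), 0L)
    expect_identical(nrow(variantTable(empty$strata$EUR)), 0L)
})
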