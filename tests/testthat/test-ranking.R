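est <- function(id, par, locus = id, ancestry = "EUR") {
    data.frame(variant_id = id, locus = locus, ancestry = ancestry,
               raf = 0.3, odds_ratio = 1 + par, par = par, rank = 0L,
               stringsAsFactors = FALSE)
}

test_that("ranks run densely from the highest PAR down", {
    e <- rbind(est("a", 0.30), est("b", 0.10), est("c", 0.25))
    r <- rankWithinAncestry(e)
    expect_identical(r$variant_id, c("a", "c", "b"))
    expect_identical(r$rank, c(1L, 2L, 3L))

    tied <- rbind(est("a", 0.2), est("b", 0.2), est("c", 0.2))
    expect_identical(rankWithinAncestry(tied)$rank, rep(1L, 3))
    expect_identical(rankWithinAncestry(est("solo", 0.5))$rank, 1L)
    expect_error(rankWithinAncestry(rbind(est("a", 0.1),
                                          est("b", 0.1, ancestry = "AFR"))),
                 "single ancestry")
})

test_that("ranking is invariant to input permutation", {
    set.seed(61)
    e <- do.call(rbind, lapply(1:20, function(i)
        est(sprintf("v%02d", i), round(runif(1), 2))))
    ref <- rankWithinAncestry(e)
    for (i in 1:5)
        expect_identical(rankWithinAncestry(e[sample.int(nrow(e)), ]), ref)
})

test_that("the comparison matrix spans the union of loci with absent cells", {
    eur <- rankWithinAncestry(rbind(est("v1", 0.3, "APOE"),
                                    est("v2", 0.1, "BIN1"),
                                    est("v3", 0.05, "CR1")))
    afr <- rankWithinAncestry(est("v4", 0.2, "APOE", "AFR"))
    cmp <- buildComparison(list(EUR = eur, AFR = afr))
    expect_identical(dim(parMatrix(cmp)), c(3L, 2L))
    expect_identical(sum(is.na(parMatrix(cmp))), 2L)
    expect_identical(rownames(parMatrix(cmp))[1], "APOE")
    ## present cells = sum of per-ancestry estimates
    expect_identical(sum(!is.na(parMatrix(cmp))), nrow(eur) + nrow(afr))
    ## rank/PAR cells absent together, ranks dense per column
    expect_identical(is.na(parMatrix(cmp)), is.na(rankMatrix(cmp)))
    expect_identical(rankMatrix(cmp)[, "EUR"][!is.na(rankMatrix(cmp)[, "EUR"])],
                     c(APOE = 1L, BIN1 = 2L, CR1 = 3L))

    solo <- buildComparison(list(EUR = eur))
    expect_identical(dim(parMatrix(solo)), c(3L, 1L))

    ## permuting ancestry order only permutes columns
    cmp2 <- buildComparison(list(AFR = afr, EUR = eur))
    expect_identical(parMatrix(cmp2)[, c("EUR", "AFR")],
                     parMatrix(cmp)[, c("EUR", "AFR")])

    dup <- rbind(est("v1", 0.3, "APOE"), est("v9", 0.2, "APOE"))
    expect_error(buildComparison(list(EUR = dup)), "duplicate locus")
})

test_that("long format carries one row per present cell", {
    eur <- rankWithinAncestry(rbind(est("v1", 0.3, "APOE"),
                                    est("v2", 0.1, "BIN1")))
    afr <- rankWithinAncestry(est("v4", 0.2, "APOE", "AFR"))
    long <- comparisonToLong(buildComparison(list(EUR = eur, AFR = afr)))
    expect_identical(nrow(long), 3L)
    expect_identical(names(long), c("locus", "ancestry", "par", "rank"))
})

test_that("loci classify as universal, enriched or single, monotone in topK", {
    mk <- function() {
        eur <- rankWithinAncestry(rbind(est("v1", 0.3, "APOE"),
                                        est("v2", 0.2, "BIN1"),
                                        est("v3", 0.1, "CR1"),
                                        est("v4", 0.05, "ABCA7")))
        afr <- rankWithinAncestry(rbind(est("v5", 0.25, "APOE", "AFR"),
                                        est("v6", 0.22, "TREM2", "AFR"),
                                        est("v7", 0.02, "BIN1", "AFR")))
        buildComparison(list(EUR = eur, AFR = afr))
    }
    cmp <- mk()
    cls <- classifyLoci(cmp, topK = 2, minAncestries = 2)
    expect_identical(unname(cls["APOE"]), "universal")
    expect_identical(unname(cls["BIN1"]), "enriched:EUR")
    expect_identical(unname(cls["CR1"]), "single")
    expect_identical(unname(cls["TREM2"]), "single")

    ## enlarging topK never demotes a universal locus
    for (k in 3:4) {
        cls2 <- classifyLoci(cmp, topK = k, minAncestries = 2)
        expect_true(all(names(cls)[cls == "universal"] %in%
                        names(cls2)[cls2 == "universal"]))
    }
    expect_identical(unname(classifyLoci(cmp, topK = 3,
                                         minAncestries = 2)["BIN1"]),
                     "universal")
})
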