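makeBlock <- function(betas, ses, locus = "L", ld = NULL) {
    n <- length(betas)
    df <- data.frame(variant_id = sprintf("v%d", seq_len(n)),
                     chrom = "1", pos = seq_len(n),
                     effect_allele = "A", other_allele = "G",
                     beta = betas, se = ses,
                     p_value = pmax(2 * pnorm(-abs(betas / ses)), 1e-300),
                     eaf = 0.3, locus = locus, ancestry = "EUR",
                     risk_allele = "A", odds_ratio = exp(abs(betas)),
                     raf = 0.3, flipped = FALSE,
                     stringsAsFactors = FALSE)
    new("LocusBlock", locus = locus, ancestry = "EUR", variants = df,
        ld = ld)
}

test_that("the approximate Bayes factor matches its null case and a quadrature oracle", {
    expect_equal(abf(0, se = 0.1, priorSd = 0.2), sqrt(0.01 / 0.05),
                 tolerance = 1e-12)
    expect_identical(abf(0.2, 0.05, 0.2), abf(0.2, 0.05, 0.2))
    expect_equal(abf(0.25, se = 0.05, priorSd = 0.2),
                 quadratureBF(0.25, 0.05, 0.2), tolerance = 1e-9)
    ## sign enters only through z^2
    expect_equal(abf(-0.25, 0.05, 0.2), abf(0.25, 0.05, 0.2))
    expect_error(abf(0.1, se = 0), "se")
    expect_error(abf(Inf, se = 0.1), "finite")
})

test_that("single-causal posteriors normalize, rank by evidence, and match quadrature", {
    one <- finemapLocus(makeBlock(0.3, 0.05))
    expect_equal(pipTable(one)$pip, 1)
    expect_true(pipTable(one)$high_confidence)

    twin <- finemapLocus(makeBlock(c(0.2, 0.2), c(0.04, 0.04)))
    expect_equal(pipTable(twin)$pip, c(0.5, 0.5))
    expect_false(any(pipTable(twin)$high_confidence))

    ## z = 6 vs z = 2 at se 0.05: posteriors from the quadrature oracle
    res <- finemapLocus(makeBlock(c(6, 2) * 0.05, c(0.05, 0.05)))
    bf <- c(quadratureBF(0.30, 0.05, 0.2), quadratureBF(0.10, 0.05, 0.2))
    expect_equal(pipTable(res)$pip, bf / sum(bf), tolerance = 1e-9)
    expect_gt(pipTable(res)$pip[1], 0.99)
})

test_that("log-space normalization survives extreme z-scores", {
    res <- finemapLocus(makeBlock(c(60 * 0.05, 0.01), c(0.05, 0.05)))
    p <- pipTable(res)$pip
    expect_true(all(is.finite(p)))
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_gt(p[1], 1 - 1e-12)
})

test_that("credible sets are the smallest descending-PIP prefix reaching 95%", {
    set.seed(51)
    for (i in 1:10) {
        n <- sample(2:15, 1)
        res <- pipTable(finemapLocus(makeBlock(rnorm(n, 0, 0.1),
                                               runif(n, 0.02, 0.1))))
        expect_equal(sum(res$pip), 1, tolerance = 1e-9)
        ord <- order(-res$pip)
        k <- sum(res$in_credible_set_95)
        expect_true(all(res$in_credible_set_95[ord[seq_len(k)]]))
        expect_gte(sum(res$pip[ord[seq_len(k)]]), 0.95 - 1e-9)
        if (k > 1)
            expect_lt(sum(res$pip[ord[seq_len(k - 1)]]), 0.95)
        ## at a threshold >= 0.5 at most one variant can be flagged
        expect_lte(sum(res$pip > 0.8), 1)
        expect_identical(res$high_confidence, res$pip > 0.8)
    }
})

test_that("block-level validity and grouping across loci behave", {
    expect_error(finemapLocus(makeBlock(0.3, 0.05), ppThreshold = 1.2),
                 "ppThreshold")
    badLD <- matrix(c(1, 0.5, 0.9, 1), 2)
    expect_error(makeBlock(c(0.1, 0.2), c(0.05, 0.05), ld = badLD),
                 "symmetric")

    df <- rbind(variantTable(makeBlock(c(0.3, 0.1), c(0.05, 0.05), "L1")),
                variantTable(makeBlock(c(0.2, 0.2), c(0.05, 0.05), "L2")))
    all_ <- finemapAllLoci(df)
    expect_identical(nrow(all_), 4L)
    expect_equal(as.numeric(tapply(all_$pip, all_$locus, sum)), c(1, 1),
                 tolerance = 1e-9)
})
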