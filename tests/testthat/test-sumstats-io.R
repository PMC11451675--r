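test_that("well-formed tables load with order preserved, on either delimiter", {
    set.seed(11)
    df <- randomVariantFrame(3)
    tf <- tempfile(fileext = ".tsv")
    writeSumstatsTable(df[, setdiff(names(df), "ancestry")], tf)
    st <- readSumstats(tf, "EUR")
    expect_s4_class(st, "AncestryStratum")
    expect_identical(variantTable(st)$variant_id, df$variant_id)
    expect_equal(variantTable(st)$beta, signif(df$beta, 6))

    csv <- tempfile(fileext = ".csv")
    out <- df[, setdiff(names(df), "ancestry")]
    write.csv(out, csv, row.names = FALSE, quote = FALSE)
    st2 <- readSumstats(csv, "EUR")
    expect_equal(variantTable(st2)$pos, df$pos)
})

test_that("odds-ratio inputs are converted to beta on read", {
    tf <- tempfile()
    writeLines(c("variant_id\tchrom\tpos\teffect_allele\tother_allele\todds_ratio\tse\tp_value\teaf\tlocus",
                 "rs1\t1\t100\tA\tG\t1.0\t0.05\t0.5\t0.3\tL1",
                 "rs2\t1\t200\tC\tT\t2.0\t0.05\t1e-8\t0.2\tL1"), tf)
    st <- readSumstats(tf, "EUR")
    expect_equal(variantTable(st)$beta, c(0, log(2)), tolerance = 1e-6)
})

test_that("invalid rows are rejected and the rest loaded; schema errors are fatal", {
    set.seed(12)
    df <- randomVariantFrame(4)
    df$eaf[2] <- 1.2
    tf <- tempfile()
    writeSumstatsTable(df[, setdiff(names(df), "ancestry")], tf)
    expect_message(st <- readSumstats(tf, "EUR"), "dropped 1 invalid")
    expect_identical(variantTable(st)$variant_id, df$variant_id[-2])

    df2 <- df[, setdiff(names(df), c("ancestry", "se"))]
    tf2 <- tempfile()
    writeSumstatsTable(df2, tf2)
    expect_error(readSumstats(tf2, "EUR"), "se")

    ## >50% failures abort
    df3 <- randomVariantFrame(4)
    df3$se[1:3] <- -1
    tf3 <- tempfile()
    writeSumstatsTable(df3[, setdiff(names(df3), "ancestry")], tf3)
    expect_error(readSumstats(tf3, "EUR"), "abort")
})

test_that("write/read round trip reproduces every field to 6 significant digits", {
    set.seed(13)
    for (n in c(0L, 1L, 25L)) {
        df <- randomVariantFrame(n)
        tf <- tempfile()
        writeSumstatsTable(df, tf)
        expect_identical(length(readLines(tf)), n + 1L)
        if (n == 0L) next
        back <- readSumstatsTable(tf)
        for (col in names(df)) {
            if (is.double(df[[col]]))
                expect_equal(back[[col]], signif(df[[col]], 6),
                             tolerance = 1e-12)
            else expect_equal(back[[col]], df[[col]])
        }
    }
})

test_that("every emitted record satisfies the type invariants under random corruption", {
    set.seed(14)
    for (rep in 1:20) {
        df <- randomVariantFrame(30)
        ## corrupt a random subset of rows in random ways
        k <- sample.int(10L, 1L)
        rows <- sample.int(nrow(df), k)
        for (i in rows) {
            switch(sample.int(4L, 1L),
                   df$eaf[i] <- sample(c(0, 1, 1.5, -0.2), 1L),
                   df$se[i] <- sample(c(0, -0.1), 1L),
                   df$other_allele[i] <- df$effect_allele[i],
                   df$p_value[i] <- sample(c(0, 1.7), 1L))
        }
        tf <- tempfile()
        writeSumstatsTable(df[, setdiff(names(df), "ancestry")], tf)
        st <- suppressMessages(readSumstats(tf, "EUR"))
        v <- variantTable(st)
        expect_true(all(v$eaf > 0 & v$eaf < 1))
        expect_true(all(v$se > 0))
        expect_true(all(v$p_value > 0 & v$p_value <= 1))
        expect_true(all(v$effect_allele != v$other_allele))
    }
})

test_that("proxy maps must be injective and never self-referential", {
    tf <- tempfile()
    writeLines(c("target\tproxy\tjustification",
                 "rs7412\trs1065853\ttight LD in reference panels"), tf)
    pm <- readProxyMap(tf)
    expect_identical(pm$proxy, "rs1065853")

    writeLines(c("target\tproxy", "rsA\trsA"), tf)
    expect_error(readProxyMap(tf), "itself")
    writeLines(c("target\tproxy", "rsA\trsC", "rsB\trsC"), tf)
    expect_error(readProxyMap(tf), "injective")
})
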