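## Case-control allele-count model shared by the generator.
##
## Alleles are the sampling unit (2N per arm, HWE). Given a population risk
## allele frequency f, a per-allele risk ratio OR and a disease prevalence K,
## the baseline per-allele incidence is r0 = K / (1 + f (OR - 1)); case and
## control allele frequencies follow by Bayes:
##   p_case = OR f / (1 + f (OR - 1))
##   p_ctrl = f (1 - OR r0) / (1 - K)   (~ f when the disease is rare)
.armFrequencies <- function(f, or, prevalence) {
    r0 <- prevalence / (1 + f * (or - 1))
    list(pCase = or * f / (1 + f * (or - 1)),
         pCtrl = f * (1 - or * r0) / (1 - prevalence))
}

.waldFromCounts <- function(a, b, c, d) {
    if (min(a, b, c, d) == 0) { a <- a + 0.5; b <- b + 0.5
                                c <- c + 0.5; d <- d + 0.5 }
    beta <- log((a * d) / (b * c))
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    z <- beta / se
    ## keep extreme signals representable: p stays strictly positive
    list(beta = beta, se = se,
         p = max(2 * stats::pnorm(-abs(z)), .Machine$double.xmin))
}

#' Expected Wald z-score of a simulated variant
#'
#' Expected allelic Wald z for the generator's case-control model, from
#' the expected 2x2 allele counts. Used to position the causal signal in
#' simulated locus blocks and to choose sample sizes that deliver a target
#' signal strength.
#'
#' @param nCases,nControls individuals per arm.
#' @param trueRaf population risk allele frequency in (0, 1).
#' @param trueOr per-allele odds ratio > 0.
#' @param prevalence disease prevalence in (0, 0.5).
#' @return list with `z` (expected Wald z), `se` (expected standard
#'   error of log OR) and the arm frequencies.
#' @export
expectedWaldZ <- function(nCases, nControls, trueRaf, trueOr,
                          prevalence = 0.005) {
    fr <- .armFrequencies(trueRaf, trueOr, prevalence)
    a <- 2 * nCases * fr$pCase
    b <- 2 * nCases * (1 - fr$pCase)
    c <- 2 * nControls * fr$pCtrl
    d <- 2 * nControls * (1 - fr$pCtrl)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    list(z = log((a * d) / (b * c)) / se, se = se,
         pCase = fr$pCase, pCtrl = fr$pCtrl)
}

.flipOrientation <- function(rec) {
    tmp <- rec$effect_allele
    rec$effect_allele <- rec$other_allele
    rec$other_allele <- tmp
    rec$eaf <- 1 - rec$eaf
    rec$beta <- -rec$beta
    rec
}

#' Simulate one variant's summary statistics
#'
#' Draws case and control risk-allele counts binomially under the
#' allele-count case-control model (see [expectedWaldZ()]), then computes
#' the sample log odds ratio (Haldane-Anscombe 0.5 correction when a cell
#' is zero), its standard error, the two-sided Wald p-value, and the
#' pooled sample frequency of the designated effect allele. With
#' probability `protectiveFraction` the record is emitted in the flipped
#' (protective-looking) orientation: alleles swapped, frequency
#' complemented, beta negated — exactly what [harmonizeVariants()] undoes.
#'
#' Uses the session RNG; seed upstream (e.g. via [simulateStudy()]).
#'
#' @inheritParams expectedWaldZ
#' @param variantId,chrom,pos,locus,ancestry identifiers for the record.
#' @param protectiveFraction probability of flipped emission, in [0, 1].
#' @return one-row data.frame with the [AncestryStratum-class] columns.
#' @export
simulateSingleVariant <- function(nCases, nControls, trueRaf, trueOr,
                                  variantId = "rs1", chrom = "1",
                                  pos = 1L, locus = "LOCUS",
                                  ancestry = "EUR",
                                  prevalence = 0.005,
                                  protectiveFraction = 0) {
    stopifnot(nCases >= 1, nControls >= 1, trueOr > 0,
              trueRaf > 0, trueRaf < 1,
              prevalence > 0, prevalence < 0.5)
    fr <- .armFrequencies(trueRaf, trueOr, prevalence)
    for (attempt in seq_len(100L)) {
        a <- stats::rbinom(1L, 2L * nCases, fr$pCase)
        c <- stats::rbinom(1L, 2L * nControls, fr$pCtrl)
        if ((a + c) > 0 && (a + c) < 2 * (nCases + nControls)) break
        if (attempt == 100L)
            stop("monomorphic draws for ", variantId, " after 100 attempts")
    }
    b <- 2L * nCases - a
    d <- 2L * nControls - c
    w <- .waldFromCounts(a, b, c, d)
    rec <- data.frame(variant_id = variantId, chrom = chrom,
                      pos = as.integer(pos),
                      effect_allele = "A", other_allele = "G",
                      beta = w$beta, se = w$se, p_value = w$p,
                      eaf = (a + c) / (2 * (nCases + nControls)),
                      locus = locus, ancestry = ancestry,
                      stringsAsFactors = FALSE)
    if (protectiveFraction > 0 && stats::runif(1L) < protectiveFraction)
        rec <- .flipOrientation(rec)
    rec
}

#' Simulate a locus block with LD structure
#'
#' Simulates the z-scores of a locus's variants directly at the
#' summary-statistic level: with AR(1) LD matrix R (R_ij = rho^|i-j|) and
#' a single causal variant whose expected z is lambda (from its odds
#' ratio, frequency and the sample sizes via [expectedWaldZ()]), the
#' z-vector is drawn from MVN(R lambda e_causal, R). Each z is converted
#' back to (beta, se, p) using the allelic standard error at that
#' variant's frequency. Records are harmonized and packaged as a
#' [LocusBlock-class] carrying R; variant ids are `<locus>_v<i>` so the
#' causal variant is identifiable in recovery tests.
#'
#' @inheritParams simulateSingleVariant
#' @param nVariants number of variants in the block.
#' @param causalIndex 1-based index of the causal variant.
#' @param ldRho AR(1) LD parameter in [0, 1).
#' @param chrom,posStart placement of the block.
#' @return A [LocusBlock-class] of harmonized variants with its LD matrix.
#' @export
simulateLocusBlock <- function(nVariants, causalIndex, trueRaf, trueOr,
                               ldRho, nCases, nControls,
                               locus = "LOCUS", ancestry = "EUR",
                               chrom = "1", posStart = 1e6,
                               prevalence = 0.005,
                               protectiveFraction = 0) {
    if (ldRho < 0 || ldRho >= 1) stop("ldRho must lie in [0, 1)")
    if (causalIndex < 1 || causalIndex > nVariants)
        stop("causalIndex out of range")
    R <- ldRho^abs(outer(seq_len(nVariants), seq_len(nVariants), "-"))
    lambda <- expectedWaldZ(nCases, nControls, trueRaf, trueOr,
                            prevalence)$z
    mu <- R[, causalIndex] * lambda
    z <- mu + as.vector(t(chol(R)) %*% stats::rnorm(nVariants))

    f <- stats::runif(nVariants, 0.1, 0.9)
    f[causalIndex] <- trueRaf
    se <- sqrt((1 / (2 * nCases) + 1 / (2 * nControls)) / (f * (1 - f)))
    df <- data.frame(variant_id = sprintf("%s_v%d", locus,
                                          seq_len(nVariants)),
                     chrom = chrom,
                     pos = as.integer(posStart + 1000 *
                                      (seq_len(nVariants) - 1L)),
                     effect_allele = "A", other_allele = "G",
                     beta = z * se, se = se,
                     p_value = pmax(2 * stats::pnorm(-abs(z)),
                                    .Machine$double.xmin),
                     eaf = f, locus = locus, ancestry = ancestry,
                     stringsAsFactors = FALSE)
    if (protectiveFraction > 0) {
        flip <- stats::runif(nVariants) < protectiveFraction
        for (i in which(flip)) df[i, ] <- .flipOrientation(df[i, ])
    }
    new("LocusBlock", locus = locus, ancestry = ancestry,
        variants = harmonizeVariants(df), ld = R)
}

#' Build a simulation configuration
#'
#' Describes a multi-ancestry case-control study with known ground truth.
#' Each locus entry gives its variant count, causal index, AR(1) LD
#' parameter, and per-ancestry true odds ratio and risk allele frequency
#' (scalars are recycled across ancestries).
#'
#' @param seed integer RNG seed making the whole study reproducible.
#' @param ancestries list of `list(label, n_cases, n_controls)`.
#' @param loci list of `list(label, n_variants, causal_index, ld_rho,
#'   true_or, true_raf)` where `true_or`/`true_raf` are single values or
#'   vectors named by ancestry label.
#' @param prevalence disease prevalence (default 0.005).
#' @param protectiveFraction fraction of records emitted in flipped
#'   (protective-looking) orientation (default 0.3).
#' @return validated configuration list for [simulateStudy()].
#' @export
simulationConfig <- function(seed, ancestries, loci, prevalence = 0.005,
                             protectiveFraction = 0.3) {
    stopifnot(length(seed) == 1L, is.finite(seed),
              prevalence > 0, prevalence < 0.5,
              protectiveFraction >= 0, protectiveFraction <= 1)
    for (a in ancestries)
        stopifnot(!is.null(a$label), a$n_cases >= 1, a$n_controls >= 1)
    for (l in loci) {
        stopifnot(!is.null(l$label), l$n_variants >= 1,
                  l$causal_index >= 1, l$causal_index <= l$n_variants,
                  all(l$true_or > 0),
                  all(l$true_raf > 0), all(l$true_raf < 1))
        if (is.null(l$ld_rho)) l$ld_rho <- 0
        stopifnot(l$ld_rho >= 0, l$ld_rho < 1)
    }
    structure(list(seed = as.integer(seed), ancestries = ancestries,
                   loci = loci, prevalence = prevalence,
                   protective_fraction = protectiveFraction),
              class = "simulation_config")
}

.perAncestry <- function(x, label) {
    if (!is.null(names(x)) && label %in% names(x)) unname(x[[label]])
    else unname(x[[1L]])
}

#' Simulate a full multi-ancestry study
#'
#' Generates per-ancestry summary-statistics strata plus a ground-truth
#' table (true OR, true RAF, causal variant id, and the true PAR obtained
#' by [computePAR()] on the risk-oriented generating parameters) for
#' recovery tests. Deterministic given `cfg$seed`. Single-variant loci go
#' through [simulateSingleVariant()]; multi-variant loci through
#' [simulateLocusBlock()].
#'
#' @param cfg a configuration from [simulationConfig()] (or an equivalent
#'   list, e.g. parsed from YAML).
#' @param outputDir optional directory; when given, each stratum is
#'   written as `sumstats_<label>.tsv` and the truth as `truth.tsv`.
#' @return list with `strata` (named list of [AncestryStratum-class]),
#'   `blocks` (list of [LocusBlock-class] for multi-variant loci) and
#'   `truth` (data.frame).
#' @export
simulateStudy <- function(cfg, outputDir = NULL) {
    if (!inherits(cfg, "simulation_config"))
        cfg <- simulationConfig(cfg$seed, cfg$ancestries, cfg$loci,
                                cfg$prevalence %||% 0.005,
                                cfg$protective_fraction %||% 0.3)
    set.seed(cfg$seed)
    strata <- list()
    blocks <- list()
    truth <- list()
    for (a in cfg$ancestries) {
        rows <- list()
        chromCounter <- 0L
        for (l in cfg$loci) {
            chromCounter <- chromCounter + 1L
            or <- .perAncestry(l$true_or, a$label)
            raf <- .perAncestry(l$true_raf, a$label)
            if (l$n_variants == 1L) {
                rec <- simulateSingleVariant(
                    a$n_cases, a$n_controls, raf, or,
                    variantId = paste0(l$label, "_v1"),
                    chrom = as.character(chromCounter), pos = 1e6,
                    locus = l$label, ancestry = a$label,
                    prevalence = cfg$prevalence,
                    protectiveFraction = cfg$protective_fraction)
                causalId <- rec$variant_id
                rows[[length(rows) + 1L]] <- rec
            } else {
                blk <- simulateLocusBlock(
                    l$n_variants, l$causal_index, raf, or,
                    l$ld_rho %||% 0, a$n_cases, a$n_controls,
                    locus = l$label, ancestry = a$label,
                    chrom = as.character(chromCounter),
                    prevalence = cfg$prevalence,
                    protectiveFraction = cfg$protective_fraction)
                blocks[[length(blocks) + 1L]] <- blk
                v <- variantTable(blk)
                causalId <- v$variant_id[l$causal_index]
                ## re-emit in reported (possibly protective) orientation:
                ## the stratum stores records as a study would publish them
                rep_ <- v[, .VARIANT_COLS]
                for (i in which(v$flipped))
                    rep_[i, ] <- .flipOrientation(rep_[i, ])
                rows[[length(rows) + 1L]] <- rep_
            }
            riskOr <- if (or >= 1) or else 1 / or
            riskRaf <- if (or >= 1) raf else 1 - raf
            truth[[length(truth) + 1L]] <- data.frame(
                locus = l$label, ancestry = a$label,
                causal_variant = causalId, true_or = or,
                true_raf = raf, true_par = computePAR(riskRaf, riskOr),
                stringsAsFactors = FALSE)
        }
        df <- if (length(rows)) do.call(rbind, rows) else .emptyVariantFrame()
        rownames(df) <- NULL
        strata[[a$label]] <- new("AncestryStratum", label = a$label,
                                 variants = df,
                                 sourceName = sprintf("synthetic seed %d",
                                                      cfg$seed))
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
        data.frame(locus = character(), ancestry = character(),
                   causal_variant = character(), true_or = numeric(),
                   true_raf = numeric(), true_par = numeric(),
                   stringsAsFactors = FALSE)
    if (!is.null(outputDir)) {
        dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
        for (lab in names(strata))
            writeSumstatsTable(variantTable(strata[[lab]]),
                               file.path(outputDir,
                                         sprintf("sumstats_%s.tsv", lab)))
        writeSumstatsTable(truth, file.path(outputDir, "truth.tsv"))
    }
    list(strata = strata, blocks = blocks, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.emptyVariantFrame <- function() {
    data.frame(variant_id = character(), chrom = character(),
               pos = integer(), effect_allele = character(),
               other_allele = character(), beta = numeric(),
               se = numeric(), p_value = numeric(), eaf = numeric(),
               locus = character(), ancestry = character(),
               stringsAsFactors = FALSE)
}
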