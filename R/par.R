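#' Levin's population attributable risk
#'
#' Computes the population attributable risk (PAR) of a risk allele,
#'
#' \deqn{PAR = \frac{p\,(OR - 1)}{p\,(OR - 1) + 1}}
#'
#' where `p` is the risk allele frequency and `OR` the per-allele odds
#' ratio (used in place of the relative risk, as is standard for
#' case-control summary statistics under the rare-disease assumption).
#' The exposure unit is the allele: `p` is the RAF itself, not a carrier
#' frequency.
#'
#' PAR is 0 exactly when OR = 1, is strictly increasing in each argument,
#' and is bounded in [0, 1).
#'
#' @param raf risk allele frequency, in (0, 1].
#' @param oddsRatio per-allele odds ratio, >= 1 (harmonization guarantees
#'   this upstream).
#' @return PAR value(s) in [0, 1); vectorized over both arguments.
#' @examples
#' computePAR(0.15, 3)      # 0.2307692...
#' computePAR(0.5, 1)       # 0: null effect
#' @export
computePAR <- function(raf, oddsRatio) {
    if (any(!is.finite(raf)) || any(!is.finite(oddsRatio)))
        stop("raf and oddsRatio must be finite")
    if (any(raf <= 0 | raf > 1))
        stop("raf must lie in (0, 1]")
    if (any(oddsRatio < 1))
        stop("oddsRatio must be >= 1; harmonize variants first")
    x <- raf * (oddsRatio - 1)
    x / (x + 1)
}

#' PAR for a table of harmonized variants
#'
#' Applies [computePAR()] to each harmonized variant, producing one
#' attributable-risk estimate per row, order preserved. The `rank` column
#' is initialised to 0 and assigned later by [rankWithinAncestry()].
#'
#' @param df data.frame of harmonized variants (columns `raf`,
#'   `odds_ratio` present).
#' @return data.frame with columns `variant_id`, `locus`, `ancestry`,
#'   `raf`, `odds_ratio`, `par`, `rank`.
#' @export
parForVariants <- function(df) {
    if (!nrow(df))
        return(data.frame(variant_id = character(), locus = character(),
                          ancestry = character(), raf = numeric(),
                          odds_ratio = numeric(), par = numeric(),
                          rank = integer(), stringsAsFactors = FALSE))
    par <- tryCatch(computePAR(df$raf, df$odds_ratio), error = function(e) {
        bad <- which(df$raf <= 0 | df$raf > 1 | df$odds_ratio < 1)
        stop("PAR domain error at variant(s): ",
             paste(utils::head(df$variant_id[bad], 5), collapse = ", "),
             " (", conditionMessage(e), ")", call. = FALSE)
    })
    data.frame(variant_id = df$variant_id, locus = df$locus,
               ancestry = df$ancestry, raf = df$raf,
               odds_ratio = df$odds_ratio, par = par, rank = 0L,
               stringsAsFactors = FALSE)
}

#' Attributable fraction from an enumerated closed population
#'
#' Brute-force reference for Levin's formula: enumerates a closed
#' population with exposure prevalence `p` and relative risk `rr` at a
#' fixed baseline incidence, and returns the attributable fraction
#' (I_pop - I_unexposed) / I_pop computed from the case counts. Used as an
#' independent check of [computePAR()]; it shares no code with it.
#'
#' @param p exposure prevalence in (0, 1].
#' @param rr relative risk >= 1.
#' @param n population size for the enumeration.
#' @param baseline baseline (unexposed) incidence.
#' @return attributable fraction in [0, 1).
#' @export
attributableFractionByEnumeration <- function(p, rr, n = 1e6,
                                              baseline = 0.01) {
    nExposed <- p * n
    nUnexposed <- n - nExposed
    casesExposed <- nExposed * baseline * rr
    casesUnexposed <- nUnexposed * baseline
    iPop <- (casesExposed + casesUnexposed) / n
    iUnexposed <- baseline
    (iPop - iUnexposed) / iPop
}
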