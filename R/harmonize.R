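#' Orient variants to their risk allele
#'
#' Re-orients every reported effect so that the effect allele is the risk
#' allele. Risk variants (beta > 0, OR > 1) keep their reported effect
#' allele and the risk allele frequency (RAF) equals the reported
#' effect-allele frequency. Protective variants (beta < 0, OR < 1) are
#' allele-flipped: the risk allele becomes the reported other allele and
#' RAF = 1 - reported frequency. The harmonized odds ratio is
#' exp(|beta|) >= 1. A null effect (beta exactly 0) is kept unflipped with
#' OR = 1; it contributes zero attributable risk downstream.
#'
#' Harmonization is idempotent: applying it to already-harmonized effects
#' changes nothing. `p_value`, `se`, `locus` and `ancestry` pass through
#' untouched.
#'
#' @param df data.frame of variant records (the columns of
#'   [AncestryStratum-class]).
#' @return The input with `beta` replaced by |beta| and added columns
#'   `risk_allele`, `odds_ratio`, `raf`, `flipped`; effect/other alleles
#'   and `eaf` are rewritten in risk-allele orientation. Row order
#'   preserved.
#' @examples
#' v <- data.frame(variant_id = "rs1", chrom = "1", pos = 1L,
#'                 effect_allele = "A", other_allele = "G",
#'                 beta = -0.3, se = 0.05, p_value = 1e-8, eaf = 0.2,
#'                 locus = "L1", ancestry = "EUR")
#' harmonizeVariants(v)[, c("risk_allele", "raf", "odds_ratio", "flipped")]
#' @export
harmonizeVariants <- function(df) {
    chk <- .checkVariantFrame(df)
    if (!isTRUE(chk)) stop("invalid variant table: ", paste(chk, collapse = "; "))
    flip <- df$beta < 0
    out <- df
    out$flipped <- flip
    out$risk_allele <- ifelse(flip, df$other_allele, df$effect_allele)
    other <- ifelse(flip, df$effect_allele, df$other_allele)
    out$effect_allele <- out$risk_allele
    out$other_allele <- other
    out$raf <- ifelse(flip, 1 - df$eaf, df$eaf)
    out$eaf <- out$raf
    out$beta <- abs(df$beta)
    out$odds_ratio <- exp(out$beta)
    out[, .HARMONIZED_COLS]
}

#' Harmonize a whole ancestry stratum
#'
#' Element-wise [harmonizeVariants()] over a stratum's variants, order
#' preserved.
#'
#' @param stratum an [AncestryStratum-class].
#' @return data.frame of harmonized variants.
#' @export
harmonizeStratum <- function(stratum) {
    stopifnot(is(stratum, "AncestryStratum"))
    df <- variantTable(stratum)
    if (!nrow(df)) {
        out <- df
        for (col in setdiff(.HARMONIZED_COLS, names(out)))
            out[[col]] <- if (col == "flipped") logical() else
                if (col == "risk_allele") character() else numeric()
        return(out[, .HARMONIZED_COLS])
    }
    harmonizeVariants(df)
}
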