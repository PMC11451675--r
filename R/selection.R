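#' Keep nominally significant variants
#'
#' Retains the variants with `p_value < alpha` (default 0.05). Requiring
#' nominal significance before attributing risk increases confidence in the
#' direction of each reported effect: an effect whose sign is not
#' distinguishable from zero cannot be reliably oriented to a risk allele.
#'
#' @param df data.frame of harmonized variants.
#' @param alpha inclusion threshold in (0, 1); variants with
#'   `p_value < alpha` (strict) are kept.
#' @return The qualifying rows, order preserved.
#' @export
filterSignificant <- function(df, alpha = 0.05) {
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
        stop("alpha must be a single number in (0, 1)")
    keep <- df$p_value < alpha
    out <- df[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Select the lead variant per locus
#'
#' Picks, for each distinct locus label, the most significant variant
#' (smallest p-value). Ties are broken deterministically by larger |beta|,
#' then by lexicographically smallest `variant_id`, so permuting the input
#' never changes the selected set.
#'
#' @param df data.frame of harmonized variants with a `locus` column.
#' @return One row per distinct locus, in order of first appearance of
#'   each locus.
#' @export
selectLeadPerLocus <- function(df) {
    if (!nrow(df)) return(df)
    ord <- order(df$p_value, -abs(df$beta), df$variant_id)
    cand <- df[ord, , drop = FALSE]
    lead <- cand[!duplicated(cand$locus), , drop = FALSE]
    lead <- lead[order(match(lead$locus, unique(df$locus))), , drop = FALSE]
    rownames(lead) <- NULL
    lead
}

#' Substitute declared proxy variants
#'
#' Replaces each mapped target variant with its declared proxy's record
#' drawn from a pool (typically the full harmonized stratum before lead
#' selection). This supports the common situation where a variant of
#' interest is absent or poorly typed in one dataset and a tightly
#' correlated neighbour stands in for it. A proxy absent from the pool
#' leaves the original in place with a warning.
#'
#' @param df data.frame of harmonized variants (the selection to edit).
#' @param proxyMap data.frame with columns `target`, `proxy` (and optional
#'   `justification`), as from [readProxyMap()].
#' @param pool data.frame of harmonized variants to draw proxies from.
#' @return `df` with substitutions applied and a `proxy_for` provenance
#'   column (NA where no substitution happened).
#' @export
applyProxies <- function(df, proxyMap, pool = df) {
    out <- df
    if (!"proxy_for" %in% names(out)) out$proxy_for <- NA_character_
    if (is.null(proxyMap) || !nrow(proxyMap)) return(out)
    .validateProxyMap(proxyMap)
    for (k in seq_len(nrow(proxyMap))) {
        tgt <- proxyMap$target[k]
        prx <- proxyMap$proxy[k]
        i <- which(out$variant_id == tgt)
        if (!length(i)) next
        j <- which(pool$variant_id == prx)
        if (!length(j)) {
            warning(sprintf("proxy '%s' for '%s' absent from pool; original kept",
                            prx, tgt), call. = FALSE)
            next
        }
        repl <- pool[j[1L], intersect(names(out), names(pool)), drop = FALSE]
        for (col in names(repl)) out[i, col] <- repl[[col]]
        out$proxy_for[i] <- tgt
    }
    rownames(out) <- NULL
    out
}
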