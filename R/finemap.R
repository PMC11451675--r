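#' Wakefield approximate Bayes factor
#'
#' Closed-form Bayes factor for a single variant's association from its
#' effect estimate and standard error under a Gaussian effect prior
#' N(0, W) on the log-OR scale:
#'
#' \deqn{ABF = \sqrt{\frac{se^2}{se^2 + W}}\;
#'       \exp\!\left(\frac{z^2 W}{2\,(se^2 + W)}\right)}
#'
#' with z = beta / se and W = priorSd^2. This is the ratio of the marginal
#' likelihood of the observed estimate under the alternative to that under
#' the null, and depends on the effect sign only through z^2.
#'
#' `logABF()` returns the natural log, which is what [finemapLocus()]
#' normalizes (with max-subtraction) to avoid overflow at large z.
#'
#' @param beta effect estimate (log odds ratio).
#' @param se its standard error, > 0.
#' @param priorSd prior standard deviation of the effect, > 0
#'   (default 0.2, a weakly-informative scale for complex-trait log-ORs).
#' @return `abf()` the Bayes factor (positive, finite when inputs are);
#'   `logABF()` its natural logarithm. Both vectorized.
#' @examples
#' abf(0, se = 0.1, priorSd = 0.2)       # sqrt(0.01/0.05) = 0.4472
#' @export
abf <- function(beta, se, priorSd = 0.2) exp(logABF(beta, se, priorSd))

#' @rdname abf
#' @export
logABF <- function(beta, se, priorSd = 0.2) {
    if (any(!is.finite(beta)) || any(!is.finite(se)) || any(se <= 0))
        stop("beta must be finite and se positive")
    if (any(!is.finite(priorSd)) || any(priorSd <= 0))
        stop("priorSd must be positive")
    W <- priorSd^2
    z <- beta / se
    0.5 * log(se^2 / (se^2 + W)) + z^2 * W / (2 * (se^2 + W))
}

#' Fine-map a locus under a single-causal-variant model
#'
#' Assigns each variant in a [LocusBlock-class] a posterior inclusion
#' probability (PIP) of being the causal variant, assuming exactly one
#' causal variant per locus and a uniform prior over the variants:
#' PIP_i = ABF_i / sum_j ABF_j, computed from Wakefield log-ABFs with
#' max-subtraction. The effect sign does not matter (only z^2 enters), so
#' harmonized |beta| is used as-is. The LD matrix, when present, is not
#' consumed by this estimator — a single-causal ABF model needs only the
#' marginal estimates.
#'
#' The 95% credible set is the smallest prefix of variants sorted by
#' descending PIP whose PIPs sum to >= 0.95. Variants with
#' PIP > `ppThreshold` (default 0.80) are flagged high-confidence; at a
#' threshold >= 0.5 at most one variant per locus can be flagged.
#'
#' @param block a [LocusBlock-class].
#' @param priorSd prior SD of the log-OR effect (default 0.2).
#' @param ppThreshold posterior-probability threshold for the
#'   high-confidence flag, in (0, 1); default 0.80.
#' @return A [FineMapResult-class].
#' @export
finemapLocus <- function(block, priorSd = 0.2, ppThreshold = 0.80) {
    stopifnot(is(block, "LocusBlock"))
    if (!is.numeric(ppThreshold) || ppThreshold <= 0 || ppThreshold >= 1)
        stop("ppThreshold must lie in (0, 1)")
    df <- variantTable(block)
    if (!nrow(df)) stop("cannot fine-map an empty locus block")
    lab <- logABF(abs(df$beta), df$se, priorSd)
    w <- exp(lab - max(lab))
    pip <- w / sum(w)

    ord <- order(-pip, df$variant_id)
    csSize <- which(cumsum(pip[ord]) >= 0.95 - 1e-12)[1L]
    inCS <- logical(length(pip))
    inCS[ord[seq_len(csSize)]] <- TRUE

    res <- data.frame(variant_id = df$variant_id, pip = pip,
                      in_credible_set_95 = inCS,
                      high_confidence = pip > ppThreshold,
                      stringsAsFactors = FALSE)
    new("FineMapResult", locus = block@locus, ancestry = block@ancestry,
        results = res, priorSd = priorSd, ppThreshold = ppThreshold)
}

#' Fine-map every multi-variant locus of a harmonized table
#'
#' Groups a harmonized variant table by (ancestry, locus), wraps each
#' group as a [LocusBlock-class], and runs [finemapLocus()]. Convenience
#' for the pipeline runner.
#'
#' @param df data.frame of harmonized variants.
#' @inheritParams finemapLocus
#' @return data.frame with columns `locus`, `ancestry`, `variant_id`,
#'   `pip`, `in_credible_set_95`, `high_confidence`.
#' @export
finemapAllLoci <- function(df, priorSd = 0.2, ppThreshold = 0.80) {
    if (!nrow(df))
        return(data.frame(locus = character(), ancestry = character(),
                          variant_id = character(), pip = numeric(),
                          in_credible_set_95 = logical(),
                          high_confidence = logical()))
    groups <- split(df, list(df$ancestry, df$locus), drop = TRUE)
    out <- lapply(groups, function(g) {
        blk <- new("LocusBlock", locus = g$locus[1L],
                   ancestry = g$ancestry[1L], variants = g, ld = NULL)
        r <- pipTable(finemapLocus(blk, priorSd, ppThreshold))
        cbind(locus = g$locus[1L], ancestry = g$ancestry[1L], r,
              stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res[order(res$ancestry, res$locus, -res$pip), , drop = FALSE]
}

#' Read an LD matrix from delimited text
#'
#' Square matrix of pairwise allelic correlations with variant ids as the
#' header row and first column.
#'
#' @param path path to the delimited text matrix.
#' @return numeric matrix with dimnames.
#' @export
readLDMatrix <- function(path) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
    m <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           check.names = FALSE)
    as.matrix(m)
}
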