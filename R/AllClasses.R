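#' @import methods
NULL

## Canonical column sets shared by validity methods and the readers.
.VARIANT_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "beta", "se", "p_value", "eaf",
                   "locus", "ancestry")

.HARMONIZED_COLS <- c(.VARIANT_COLS, "risk_allele", "odds_ratio",
                      "raf", "flipped")

.PAR_COLS <- c("variant_id", "locus", "ancestry", "raf", "odds_ratio",
               "par", "rank")

.checkVariantFrame <- function(df, cols = .VARIANT_COLS) {
    msg <- character()
    missing <- setdiff(cols, names(df))
    if (length(missing))
        return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
    if (nrow(df)) {
        if (!all(df$eaf > 0 & df$eaf < 1))
            msg <- c(msg, "eaf must lie strictly in (0, 1)")
        if (!all(df$se > 0))
            msg <- c(msg, "se must be positive")
        if (!all(df$p_value > 0 & df$p_value <= 1))
            msg <- c(msg, "p_value must lie in (0, 1]")
        if (!all(df$effect_allele != df$other_allele))
            msg <- c(msg, "effect_allele and other_allele must differ")
        if (anyDuplicated(df[, c("variant_id", "ancestry")]))
            msg <- c(msg, "(variant_id, ancestry) pairs must be unique")
    }
    if (length(msg)) msg else TRUE
}

#' AncestryStratum: one ancestry's summary statistics
#'
#' Container for the per-variant GWAS summary statistics of a single
#' genetically-defined ancestry stratum (e.g. European, African/African
#' admixed, East Asian, Latino). Effects are stored on the beta (natural-log
#' odds ratio) scale; odds-ratio inputs are converted on read by
#' [readSumstats()].
#'
#' @slot label single ancestry label carried by every member variant.
#' @slot variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `p_value`, `eaf`,
#'   `locus`, `ancestry`.
#' @slot sourceName free-text provenance for the summary statistics.
#'
#' @seealso [readSumstats()], [harmonizeStratum()]
#' @exportClass AncestryStratum
setClass("AncestryStratum",
    representation(label = "character",
                   variants = "data.frame",
                   sourceName = "character"),
    prototype(label = NA_character_, sourceName = ""))

setValidity("AncestryStratum", function(object) {
    msg <- character()
    if (length(object@label) != 1L)
        msg <- c(msg, "label must be a single string")
    chk <- .checkVariantFrame(object@variants)
    if (!isTRUE(chk)) msg <- c(msg, chk)
    if (nrow(object@variants) &&
        !all(object@variants$ancestry == object@label))
        msg <- c(msg, "all variants must carry ancestry == label")
    if (length(msg)) msg else TRUE
})

#' LocusBlock: a locus's variants ready for fine-mapping
#'
#' Holds the harmonized member variants of one named locus in one ancestry,
#' with an optional square matrix of pairwise allelic correlations (r). The
#' single-causal ABF estimator does not consume the LD matrix; it is carried
#' for provenance and used by the simulator.
#'
#' @slot locus locus label (typically the nearest gene).
#' @slot ancestry ancestry label shared by all member variants.
#' @slot variants data.frame of harmonized variants (>= 1 row).
#' @slot ld square numeric correlation matrix (unit diagonal, symmetric)
#'   with dimension `nrow(variants)`, or NULL.
#'
#' @seealso [finemapLocus()], [simulateLocusBlock()]
#' @exportClass LocusBlock
setClass("LocusBlock",
    representation(locus = "character", ancestry = "character",
                   variants = "data.frame", ld = "ANY"),
    prototype(ld = NULL))

setValidity("LocusBlock", function(object) {
    msg <- character()
    if (!nrow(object@variants))
        msg <- c(msg, "a locus block needs at least one variant")
    chk <- .checkVariantFrame(object@variants, .HARMONIZED_COLS)
    if (!isTRUE(chk)) msg <- c(msg, chk)
    if (nrow(object@variants) &&
        !all(object@variants$ancestry == object@ancestry))
        msg <- c(msg, "all variants must share the block's ancestry")
    if (!is.null(object@ld)) {
        R <- object@ld
        if (!is.matrix(R) || nrow(R) != ncol(R))
            msg <- c(msg, "ld must be a square matrix")
        else {
            if (nrow(R) != nrow(object@variants))
                msg <- c(msg, "ld dimension must match the variant count")
            if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8)))
                msg <- c(msg, "ld must be symmetric")
            if (!isTRUE(all.equal(unname(diag(R)), rep(1, nrow(R)),
                                  tolerance = 1e-8)))
                msg <- c(msg, "ld must have unit diagonal")
            if (any(abs(R) > 1 + 1e-8))
                msg <- c(msg, "ld entries must lie in [-1, 1]")
        }
    }
    if (length(msg)) msg else TRUE
})

#' FineMapResult: per-variant posterior inclusion probabilities
#'
#' Result of single-causal-variant fine-mapping of one locus block: a
#' posterior inclusion probability (PIP) per variant under a uniform prior
#' across the locus, the smallest 95% credible set, and a high-confidence
#' flag for variants whose PIP exceeds the posterior-probability threshold
#' (default 0.80).
#'
#' @slot locus,ancestry labels of the fine-mapped block.
#' @slot results data.frame with columns `variant_id`, `pip`,
#'   `in_credible_set_95`, `high_confidence`.
#' @slot priorSd prior standard deviation on the log-OR effect used.
#' @slot ppThreshold posterior-probability threshold used for flagging.
#'
#' @seealso [finemapLocus()]
#' @exportClass FineMapResult
setClass("FineMapResult",
    representation(locus = "character", ancestry = "character",
                   results = "data.frame",
                   priorSd = "numeric", ppThreshold = "numeric"))

setValidity("FineMapResult", function(object) {
    msg <- character()
    need <- c("variant_id", "pip", "in_credible_set_95", "high_confidence")
    missing <- setdiff(need, names(object@results))
    if (length(missing))
        msg <- c(msg, sprintf("results missing column(s): %s",
                              paste(missing, collapse = ", ")))
    else {
        p <- object@results$pip
        if (any(p < -1e-12 | p > 1 + 1e-12))
            msg <- c(msg, "pips must lie in [0, 1]")
        if (abs(sum(p) - 1) > 1e-9)
            msg <- c(msg, "pips must sum to 1 within 1e-9")
    }
    if (length(msg)) msg else TRUE
})

#' AncestryComparison: the cross-ancestry PAR matrix
#'
#' Loci-by-ancestries grid of lead-variant PAR values (NA where a locus has
#' no qualifying variant in that ancestry) together with per-ancestry dense
#' ranks (1 = highest PAR). Rows are ordered by descending mean of the
#' present PAR values.
#'
#' @slot loci ordered locus labels (row names of the matrices).
#' @slot ancestries ordered ancestry labels (column names).
#' @slot parMatrix numeric loci x ancestries matrix of PAR values.
#' @slot rankMatrix integer matrix of per-ancestry dense ranks.
#'
#' @seealso [buildComparison()], [classifyLoci()]
#' @exportClass AncestryComparison
setClass("AncestryComparison",
    representation(loci = "character", ancestries = "character",
                   parMatrix = "matrix", rankMatrix = "matrix"))

setValidity("AncestryComparison", function(object) {
    msg <- character()
    dims <- c(length(object@loci), length(object@ancestries))
    if (!all(dim(object@parMatrix) == dims))
        msg <- c(msg, "parMatrix dimensions must match loci x ancestries")
    if (!all(dim(object@rankMatrix) == dims))
        msg <- c(msg, "rankMatrix dimensions must match loci x ancestries")
    for (j in seq_along(object@ancestries)) {
        p <- object@parMatrix[, j]
        r <- object@rankMatrix[, j]
        if (any(is.na(p) != is.na(r))) {
            msg <- c(msg, "rank and PAR cells must be absent together")
            break
        }
        ok <- !is.na(p)
        if (any(ok)) {
            expect <- match(-p[ok], sort(unique(-p[ok])))
            if (!all(r[ok] == expect)) {
                msg <- c(msg, "ranks must densely order PAR highest-to-lowest")
                break
            }
        }
    }
    if (length(msg)) msg else TRUE
})
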