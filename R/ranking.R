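#' Rank PAR estimates within one ancestry
#'
#' Assigns dense ranks to a single ancestry's PAR estimates, highest PAR
#' first: rank 1 is the largest PAR and ties share a rank. Output rows are
#' ordered by descending PAR, ties by `variant_id`.
#'
#' @param estimates data.frame of PAR estimates (from [parForVariants()]),
#'   all sharing one ancestry.
#' @return The estimates with `rank` assigned, reordered as described.
#' @export
rankWithinAncestry <- function(estimates) {
    if (!nrow(estimates)) return(estimates)
    if (length(unique(estimates$ancestry)) != 1L)
        stop("rankWithinAncestry expects estimates from a single ancestry")
    out <- estimates
    out$rank <- match(-out$par, sort(unique(-out$par)))
    out <- out[order(-out$par, out$variant_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Assemble the cross-ancestry PAR comparison
#'
#' Builds the loci-by-ancestries matrix of lead-variant PAR values over
#' the union of loci, with NA where a locus lacks a qualifying variant in
#' an ancestry, plus the matching per-ancestry dense rank matrix. Rows
#' are ordered by descending mean of the present PAR values, so the loci
#' with the broadest high attributable risk come first.
#'
#' @param perAncestry named list mapping ancestry label to its ranked PAR
#'   estimates (one row per locus, as after [selectLeadPerLocus()] +
#'   [parForVariants()] + [rankWithinAncestry()]).
#' @return An [AncestryComparison-class].
#' @export
buildComparison <- function(perAncestry) {
    if (!length(perAncestry)) stop("need at least one ancestry")
    if (is.null(names(perAncestry)) || any(!nzchar(names(perAncestry))))
        stop("perAncestry must be a named list keyed by ancestry label")
    for (anc in names(perAncestry))
        if (anyDuplicated(perAncestry[[anc]]$locus))
            stop("duplicate locus within ancestry '", anc,
                 "'; run selectLeadPerLocus first")
    loci <- unique(unlist(lapply(perAncestry, function(d) d$locus),
                          use.names = FALSE))
    ancs <- names(perAncestry)
    pm <- matrix(NA_real_, length(loci), length(ancs),
                 dimnames = list(loci, ancs))
    rm_ <- matrix(NA_integer_, length(loci), length(ancs),
                  dimnames = list(loci, ancs))
    for (anc in ancs) {
        d <- perAncestry[[anc]]
        if (!nrow(d)) next
        pm[d$locus, anc] <- d$par
        rm_[d$locus, anc] <- match(-d$par, sort(unique(-d$par)))
    }
    ord <- order(-rowMeans(pm, na.rm = TRUE), loci)
    pm <- pm[ord, , drop = FALSE]
    rm_ <- rm_[ord, , drop = FALSE]
    new("AncestryComparison", loci = rownames(pm), ancestries = ancs,
        parMatrix = pm, rankMatrix = rm_)
}

#' Flatten a comparison to long format
#'
#' One row per present (locus, ancestry) cell with its PAR and rank.
#'
#' @param cmp an [AncestryComparison-class].
#' @return data.frame with columns `locus`, `ancestry`, `par`, `rank`.
#' @export
comparisonToLong <- function(cmp) {
    stopifnot(is(cmp, "AncestryComparison"))
    pm <- parMatrix(cmp)
    rm_ <- rankMatrix(cmp)
    long <- expand.grid(locus = rownames(pm), ancestry = colnames(pm),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    long$par <- as.vector(pm)
    long$rank <- as.vector(rm_)
    long <- long[!is.na(long$par), , drop = FALSE]
    long <- long[order(long$ancestry, long$rank, long$locus), , drop = FALSE]
    rownames(long) <- NULL
    long
}

#' Classify loci as universal, population-enriched, or single-population
#'
#' Operationalizes the qualitative distinction between universally
#' applicable and population-specific genetic targets: a locus present in
#' only one ancestry is `single`; otherwise it is `universal` when it
#' ranks in the top `topK` of at least `minAncestries` ancestries, and
#' `enriched:<ancestries>` when it makes the top `topK` in at least one
#' but fewer than `minAncestries` (listing where). A multi-ancestry locus
#' that makes no top list is `background`.
#'
#' Enlarging `topK` can only promote loci (never demotes a universal one).
#'
#' @param cmp an [AncestryComparison-class].
#' @param topK rank cutoff defining a "top" signal (default 10).
#' @param minAncestries minimum number of ancestries whose top list a
#'   universal locus must reach (default: all ancestries present).
#' @return Named character vector, one entry per locus.
#' @export
classifyLoci <- function(cmp, topK = 10,
                         minAncestries = length(cmp@ancestries)) {
    stopifnot(is(cmp, "AncestryComparison"))
    if (topK < 1) stop("topK must be >= 1")
    if (minAncestries < 1 || minAncestries > length(cmp@ancestries))
        stop("minAncestries must lie in [1, number of ancestries]")
    rm_ <- rankMatrix(cmp)
    vapply(rownames(rm_), function(locus) {
        r <- rm_[locus, ]
        present <- !is.na(r)
        if (sum(present) == 1L) return("single")
        top <- present & r <= topK
        if (sum(top) >= minAncestries) return("universal")
        if (any(top))
            return(paste0("enriched:",
                          paste(colnames(rm_)[top], collapse = ",")))
        "background"
    }, character(1))
}
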