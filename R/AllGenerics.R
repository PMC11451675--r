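#' Accessors for parGWAS classes
#'
#' `variantTable()` extracts the per-variant data.frame of an
#' [AncestryStratum-class] or [LocusBlock-class]; `ancestryLabel()` the
#' ancestry label; `locusLabel()` the locus label of a [LocusBlock-class]
#' or [FineMapResult-class]; `ldMatrix()` the LD matrix of a
#' [LocusBlock-class] (or NULL); `pipTable()` the per-variant posterior
#' table of a [FineMapResult-class]; `parMatrix()` / `rankMatrix()` the
#' grids of an [AncestryComparison-class].
#'
#' @param x a parGWAS object.
#' @return The slot content described above.
#' @name accessors
#' @aliases variantTable ancestryLabel locusLabel ldMatrix pipTable
#'   parMatrix rankMatrix
NULL

#' @rdname accessors
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))

#' @rdname accessors
#' @export
setGeneric("ancestryLabel", function(x) standardGeneric("ancestryLabel"))

#' @rdname accessors
#' @export
setGeneric("locusLabel", function(x) standardGeneric("locusLabel"))

#' @rdname accessors
#' @export
setGeneric("ldMatrix", function(x) standardGeneric("ldMatrix"))

#' @rdname accessors
#' @export
setGeneric("pipTable", function(x) standardGeneric("pipTable"))

#' @rdname accessors
#' @export
setGeneric("parMatrix", function(x) standardGeneric("parMatrix"))

#' @rdname accessors
#' @export
setGeneric("rankMatrix", function(x) standardGeneric("rankMatrix"))

#' @rdname accessors
#' @export
setMethod("variantTable", "AncestryStratum", function(x) x@variants)

#' @rdname accessors
#' @export
setMethod("variantTable", "LocusBlock", function(x) x@variants)

#' @rdname accessors
#' @export
setMethod("ancestryLabel", "AncestryStratum", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("ancestryLabel", "LocusBlock", function(x) x@ancestry)

#' @rdname accessors
#' @export
setMethod("ancestryLabel", "FineMapResult", function(x) x@ancestry)

#' @rdname accessors
#' @export
setMethod("locusLabel", "LocusBlock", function(x) x@locus)

#' @rdname accessors
#' @export
setMethod("locusLabel", "FineMapResult", function(x) x@locus)

#' @rdname accessors
#' @export
setMethod("ldMatrix", "LocusBlock", function(x) x@ld)

#' @rdname accessors
#' @export
setMethod("pipTable", "FineMapResult", function(x) x@results)

#' @rdname accessors
#' @export
setMethod("parMatrix", "AncestryComparison", function(x) x@parMatrix)

#' @rdname accessors
#' @export
setMethod("rankMatrix", "AncestryComparison", function(x) x@rankMatrix)

setMethod("show", "AncestryStratum", function(object) {
    cat(sprintf("AncestryStratum '%s': %d variant(s), %d locus label(s)\n",
                object@label, nrow(object@variants),
                length(unique(object@variants$locus))))
    if (nzchar(object@sourceName))
        cat("  source:", object@sourceName, "\n")
})

setMethod("show", "LocusBlock", function(object) {
    cat(sprintf("LocusBlock '%s' [%s]: %d variant(s), LD %s\n",
                object@locus, object@ancestry, nrow(object@variants),
                if (is.null(object@ld)) "absent" else "present"))
})

setMethod("show", "FineMapResult", function(object) {
    r <- object@results
    cat(sprintf(
        "FineMapResult '%s' [%s]: %d variant(s), top PIP %.3f (%s), 95%% CS size %d\n",
        object@locus, object@ancestry, nrow(r),
        max(r$pip), r$variant_id[which.max(r$pip)],
        sum(r$in_credible_set_95)))
})

setMethod("show", "AncestryComparison", function(object) {
    cat(sprintf("AncestryComparison: %d locus/loci x %d ancestry/ancestries, %d present cell(s)\n",
                length(object@loci), length(object@ancestries),
                sum(!is.na(object@parMatrix))))
})
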