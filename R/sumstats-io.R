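#' Read a per-ancestry GWAS summary-statistics table
#'
#' Reads a delimited text table of per-variant association summary
#' statistics, validates every row, and returns an
#' [AncestryStratum-class]. The delimiter is auto-detected from the header
#' line (tab preferred, comma fallback). Effects are stored internally on
#' the beta (natural-log odds ratio) scale: if the input carries an
#' `odds_ratio` column instead of `beta`, beta = log(OR) is computed on
#' read.
#'
#' Rows violating the per-variant invariants (identical alleles, `eaf`
#' outside (0,1), non-positive `se`, `p_value` outside (0,1], non-ACGT
#' single-nucleotide alleles) are dropped with a message; if more than half
#' of the rows fail, the read aborts. A/T and C/G palindromic variants are
#' strand-ambiguous without a reference panel and are kept with a message.
#'
#' @param path path to a tab- or comma-delimited text file with a header.
#' @param ancestryLabel ancestry label to stamp on the stratum (e.g.
#'   `"EUR"`); overrides any `ancestry` column in the file.
#' @param columnMap named character vector mapping canonical field names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `beta` or `odds_ratio`, `se`, `p_value`, `eaf`, `locus`) to the
#'   file's column headers. Defaults to the canonical names themselves.
#' @param sourceName free-text provenance recorded on the stratum.
#'
#' @return An [AncestryStratum-class] whose variants all satisfy the
#'   record invariants, in file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' df <- data.frame(variant_id = c("rs1", "rs2"), chrom = "1",
#'                  pos = c(100L, 200L), effect_allele = c("A", "C"),
#'                  other_allele = c("G", "T"), beta = c(0.3, -0.1),
#'                  se = 0.05, p_value = c(1e-9, 0.04), eaf = c(0.2, 0.6),
#'                  locus = "GENE1")
#' writeSumstatsTable(df, tf)
#' readSumstats(tf, "EUR")
#' @export
readSumstats <- function(path, ancestryLabel,
                         columnMap = character(), sourceName = basename(path)) {
    if (!file.exists(path))
        stop("summary-statistics file not found: ", path)
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
    ## read everything as character ("T" alleles would otherwise parse as
    ## logical); typed conversion happens below
    raw <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             comment.char = "", quote = "\"",
                             colClasses = "character")

    canonical <- c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "se", "p_value", "eaf", "locus")
    map <- stats::setNames(canonical, canonical)
    effcol <- if ("odds_ratio" %in% names(columnMap)) "odds_ratio"
              else if ("beta" %in% names(columnMap)) "beta"
              else if ("beta" %in% names(raw)) "beta"
              else if ("odds_ratio" %in% names(raw)) "odds_ratio"
              else "beta"
    map[effcol] <- effcol
    map[names(columnMap)] <- columnMap

    missing <- setdiff(unname(map), names(raw))
    if (length(missing))
        stop("mapped column(s) absent from ", path, ": ",
             paste(missing, collapse = ", "))

    df <- data.frame(
        variant_id = as.character(raw[[map[["variant_id"]]]]),
        chrom = as.character(raw[[map[["chrom"]]]]),
        pos = as.integer(raw[[map[["pos"]]]]),
        effect_allele = toupper(as.character(raw[[map[["effect_allele"]]]])),
        other_allele = toupper(as.character(raw[[map[["other_allele"]]]])),
        beta = as.numeric(raw[[map[[effcol]]]]),
        se = as.numeric(raw[[map[["se"]]]]),
        p_value = as.numeric(raw[[map[["p_value"]]]]),
        eaf = as.numeric(raw[[map[["eaf"]]]]),
        locus = as.character(raw[[map[["locus"]]]]),
        stringsAsFactors = FALSE)
    if (effcol == "odds_ratio") {
        if (any(is.finite(df$beta) & df$beta <= 0))
            stop("odds_ratio column contains non-positive values")
        df$beta <- log(df$beta)
    }
    df$ancestry <- ancestryLabel

    nuc <- c("A", "C", "G", "T")
    bad <- !is.finite(df$beta) | !is.finite(df$se) | df$se <= 0 |
        !is.finite(df$eaf) | df$eaf <= 0 | df$eaf >= 1 |
        !is.finite(df$p_value) | df$p_value <= 0 | df$p_value > 1 |
        !(df$effect_allele %in% nuc) | !(df$other_allele %in% nuc) |
        df$effect_allele == df$other_allele |
        is.na(df$pos) | df$pos <= 0
    if (any(bad)) {
        if (mean(bad) > 0.5)
            stop(sprintf("%d of %d rows fail validation in %s; aborting",
                         sum(bad), nrow(df), path))
        message(sprintf("readSumstats: dropped %d invalid row(s) (%s)",
                        sum(bad),
                        paste(utils::head(df$variant_id[bad], 5),
                              collapse = ", ")))
        df <- df[!bad, , drop = FALSE]
        rownames(df) <- NULL
    }

    pal <- (df$effect_allele == "A" & df$other_allele == "T") |
        (df$effect_allele == "T" & df$other_allele == "A") |
        (df$effect_allele == "C" & df$other_allele == "G") |
        (df$effect_allele == "G" & df$other_allele == "C")
    if (any(pal))
        message(sprintf(
            "readSumstats: %d palindromic (A/T or C/G) variant(s) kept; strand unresolved",
            sum(pal)))

    new("AncestryStratum", label = ancestryLabel, variants = df,
        sourceName = sourceName)
}

#' Write a pipeline table to tab-delimited text
#'
#' Writes any pipeline output table (harmonized variants, PAR estimates,
#' fine-mapping posteriors, ranks) as tab-delimited text with a header
#' line. Floating-point columns are rendered with 6 significant digits, so
#' a write/read round trip reproduces every numeric field at that
#' precision.
#'
#' @param df a data.frame of records of one type.
#' @param path output path.
#' @return Invisibly, the path written.
#' @export
writeSumstatsTable <- function(df, path) {
    out <- df
    for (j in seq_along(out))
        if (is.double(out[[j]]))
            out[[j]] <- formatC(signif(out[[j]], 6), digits = 6,
                                format = "g")
    ok <- tryCatch({
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, na = "NA")
        TRUE
    }, error = function(e) e, warning = function(w) w)
    if (!isTRUE(ok))
        stop("cannot write table to ", path, ": ", conditionMessage(ok))
    invisible(path)
}

#' Read back a tab-delimited pipeline table
#'
#' Counterpart of [writeSumstatsTable()]; plain `read.table` with the
#' pipeline's conventions.
#'
#' @param path path to a tab-delimited table with a header.
#' @return data.frame.
#' @export
readSumstatsTable <- function(path) {
    hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
    charCols <- c("variant_id", "chrom", "effect_allele", "other_allele",
                  "risk_allele", "locus", "ancestry", "causal_variant",
                  "proxy_for", "class", "target", "proxy", "justification")
    cc <- ifelse(hdr %in% charCols, "character", NA)
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, quote = "\"",
                      comment.char = "", colClasses = cc)
}

#' Read a proxy-variant map
#'
#' A proxy map substitutes a correlated variant for a target variant that
#' is missing or unreliable in one dataset (for instance swapping in a
#' tightly linked SNP when the variant of interest is absent from a
#' population's summary statistics). The file is delimited text with
#' columns `target`, `proxy` and an optional `justification`.
#'
#' @param path path to the two/three-column delimited file.
#' @return data.frame with columns `target`, `proxy`, `justification`.
#' @seealso [applyProxies()]
#' @export
readProxyMap <- function(path) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
    pm <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, quote = "\"")
    if (!all(c("target", "proxy") %in% names(pm)))
        stop("proxy map needs 'target' and 'proxy' columns")
    if (!"justification" %in% names(pm)) pm$justification <- ""
    .validateProxyMap(pm)
    pm[, c("target", "proxy", "justification")]
}

.validateProxyMap <- function(pm) {
    if (any(pm$target == pm$proxy))
        stop("a proxy map entry maps a variant to itself")
    if (anyDuplicated(pm$target))
        stop("duplicate proxy-map targets")
    if (anyDuplicated(pm$proxy))
        stop("proxy map must be injective (duplicate proxies)")
    invisible(pm)
}
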