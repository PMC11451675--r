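#' Build a pipeline configuration
#'
#' Collects everything one end-to-end run needs: the per-ancestry input
#' tables, the significance threshold, an optional proxy map, the
#' fine-mapping prior and posterior threshold, the ranking knobs and the
#' output directory. `readPipelineConfig()` loads the same structure from
#' a YAML file.
#'
#' @param inputs named character vector/list mapping ancestry label to a
#'   summary-statistics file path.
#' @param outputDir directory for stage tables and the manifest.
#' @param alpha nominal-significance inclusion threshold (default 0.05).
#' @param proxyMapPath optional path to a proxy-map file
#'   ([readProxyMap()]).
#' @param priorSd,ppThreshold fine-mapping parameters ([finemapLocus()]).
#' @param topK,minAncestries locus-classification knobs
#'   ([classifyLoci()]); `minAncestries = NULL` means all ancestries.
#' @param columnMaps optional named list of per-ancestry column maps for
#'   [readSumstats()].
#' @return configuration list of class `pipeline_config`.
#' @export
pipelineConfig <- function(inputs, outputDir, alpha = 0.05,
                           proxyMapPath = NULL, priorSd = 0.2,
                           ppThreshold = 0.80, topK = 10,
                           minAncestries = NULL, columnMaps = list()) {
    inputs <- unlist(inputs)
    if (is.null(names(inputs)) || any(!nzchar(names(inputs))))
        stop("inputs must be named by ancestry label")
    missing <- inputs[!file.exists(inputs)]
    if (length(missing))
        stop("input file(s) not found: ", paste(missing, collapse = ", "))
    if (!is.null(proxyMapPath) && !file.exists(proxyMapPath))
        stop("proxy map not found: ", proxyMapPath)
    stopifnot(alpha > 0, alpha < 1, priorSd > 0,
              ppThreshold > 0, ppThreshold < 1, topK >= 1)
    structure(list(inputs = inputs, outputDir = outputDir, alpha = alpha,
                   proxyMapPath = proxyMapPath, priorSd = priorSd,
                   ppThreshold = ppThreshold, topK = topK,
                   minAncestries = minAncestries,
                   columnMaps = columnMaps),
              class = "pipeline_config")
}

#' @rdname pipelineConfig
#' @param path YAML file with the fields above (`inputs` as a mapping of
#'   ancestry label to path).
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    pipelineConfig(inputs = y$inputs,
                   outputDir = y$output_dir %||% y$outputDir %||% ".",
                   alpha = y$alpha %||% 0.05,
                   proxyMapPath = y$proxy_map %||% NULL,
                   priorSd = y$prior_sd %||% 0.2,
                   ppThreshold = y$pp_threshold %||% 0.80,
                   topK = y$top_k %||% 10,
                   minAncestries = y$min_ancestries %||% NULL,
                   columnMaps = y$column_maps %||% list())
}

#' Run the full attributable-risk pipeline
#'
#' Executes, per ancestry: read -> harmonize -> nominal-significance
#' filter -> proxy substitution -> lead-variant-per-locus selection ->
#' PAR -> within-ancestry ranking; fine-maps every multi-variant locus of
#' the filtered set; assembles the cross-ancestry comparison and locus
#' classification; and writes every stage table, the long-format
#' comparison, and a JSON manifest recording inputs, effective
#' configuration (with a hash) and per-stage row counts. Rerunning on
#' identical inputs and configuration reproduces identical outputs.
#'
#' @param cfg a `pipeline_config` from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the per-stage objects (`harmonized`,
#'   `filtered`, `selected`, `par`, `ranked`, `finemap`, `comparison`,
#'   `classification`, `manifest`).
#' @export
runPipeline <- function(cfg, quiet = FALSE) {
    stopifnot(inherits(cfg, "pipeline_config"))
    say <- function(...) if (!quiet) message(...)
    dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
    proxyMap <- if (!is.null(cfg$proxyMapPath))
        readProxyMap(cfg$proxyMapPath) else NULL

    stage <- function(name, f) {
        tryCatch(f(), error = function(e)
            stop(sprintf("[%s] %s", name, conditionMessage(e)),
                 call. = FALSE))
    }

    counts <- list()
    harmonized <- list(); filtered <- list(); selected <- list()
    parTabs <- list(); ranked <- list()
    for (anc in names(cfg$inputs)) {
        say("ancestry ", anc)
        stratum <- stage("read", function()
            readSumstats(cfg$inputs[[anc]], anc,
                         columnMap = unlist(cfg$columnMaps[[anc]]) %||%
                             character()))
        h <- stage("harmonize", function() harmonizeStratum(stratum))
        f <- stage("filter", function() filterSignificant(h, cfg$alpha))
        f <- stage("proxies", function() applyProxies(f, proxyMap, pool = h))
        s <- stage("select", function() selectLeadPerLocus(f))
        p <- stage("par", function() parForVariants(s))
        r <- stage("rank", function() rankWithinAncestry(p))
        harmonized[[anc]] <- h; filtered[[anc]] <- f
        selected[[anc]] <- s; parTabs[[anc]] <- p; ranked[[anc]] <- r
        counts[[anc]] <- list(input = nrow(variantTable(stratum)),
                              harmonized = nrow(h), filtered = nrow(f),
                              selected = nrow(s))
    }

    fm <- stage("finemap", function()
        finemapAllLoci(do.call(rbind, unname(filtered)),
                       priorSd = cfg$priorSd,
                       ppThreshold = cfg$ppThreshold))
    cmp <- stage("compare", function() buildComparison(ranked))
    cls <- stage("classify", function()
        classifyLoci(cmp, topK = cfg$topK,
                     minAncestries = cfg$minAncestries %||%
                         length(cmp@ancestries)))

    out <- function(name, df) {
        writeSumstatsTable(df, file.path(cfg$outputDir,
                                         paste0(name, ".tsv")))
    }
    out("harmonized", do.call(rbind, unname(harmonized)))
    out("filtered", do.call(rbind, unname(filtered)))
    out("selected", do.call(rbind, unname(selected)))
    out("par", do.call(rbind, unname(parTabs)))
    out("ranked", do.call(rbind, unname(ranked)))
    out("finemap", fm)
    long <- comparisonToLong(cmp)
    out("comparison", long)
    out("classification",
        data.frame(locus = names(cls), class = unname(cls),
                   stringsAsFactors = FALSE))

    effective <- cfg[c("alpha", "priorSd", "ppThreshold", "topK")]
    effective$minAncestries <- cfg$minAncestries %||%
        length(cmp@ancestries)
    cfgFile <- tempfile()
    writeLines(paste(deparse(effective), collapse = ""), cfgFile)
    manifest <- list(
        inputs = as.list(cfg$inputs),
        input_md5 = as.list(unname(tools::md5sum(unname(cfg$inputs)))),
        config = effective,
        config_hash = unname(tools::md5sum(cfgFile)),
        row_counts = counts,
        finemap_rows = nrow(fm),
        comparison_cells = sum(!is.na(parMatrix(cmp))))
    unlink(cfgFile)
    jsonlite::write_json(manifest,
                         file.path(cfg$outputDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("pipeline complete: ", cfg$outputDir)
    invisible(list(harmonized = harmonized, filtered = filtered,
                   selected = selected, par = parTabs, ranked = ranked,
                   finemap = fm, comparison = cmp, classification = cls,
                   manifest = manifest))
}
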