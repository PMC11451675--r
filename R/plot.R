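#' Bubble plot of risk allele frequency versus odds ratio
#'
#' Draws the pipeline's signature figure: risk allele frequency on the
#' x-axis, odds ratio on the y-axis, marker area linear in PAR (with a
#' floor so PAR = 0 is still visible). In `by_locus_panels` mode there is
#' one panel per ancestry with points colored by locus; in
#' `by_variant_panels` mode one panel per variant with points colored by
#' ancestry, for comparing a single signal across populations.
#'
#' The plot is fully data-determined: identical inputs give identical
#' vector output.
#'
#' @param estimates data.frame of PAR estimates (columns `variant_id`,
#'   `locus`, `ancestry`, `raf`, `odds_ratio`, `par`).
#' @param mode `"by_locus_panels"` or `"by_variant_panels"`.
#' @param sizeScale positive multiplier for the PAR-to-area mapping.
#' @param logOR plot the odds ratio on a log scale.
#' @param path optional output file; format from `format`.
#' @param format `"svg"` or `"png"`, used when `path` is given.
#' @param width,height device size in inches.
#' @return the ggplot object, invisibly when written to file.
#' @export
plotPAR <- function(estimates, mode = c("by_locus_panels",
                                        "by_variant_panels"),
                    sizeScale = 40, logOR = FALSE, path = NULL,
                    format = c("svg", "png"), width = 8, height = 6) {
    mode <- match.arg(mode)
    format <- match.arg(format)
    if (!is.numeric(sizeScale) || sizeScale <= 0)
        stop("sizeScale must be positive")
    if (is.null(estimates) || !nrow(estimates))
        stop("no estimates to plot")
    d <- estimates
    ## marker area linear in PAR with a floor; geom_point sizes by
    ## diameter, so map sqrt(area)
    d$.size <- sqrt((1 + sizeScale * d$par) / pi)
    colorVar <- if (mode == "by_locus_panels") "locus" else "ancestry"
    facetVar <- if (mode == "by_locus_panels") "ancestry" else "variant_id"
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$raf,
                                         y = .data$odds_ratio,
                                         color = .data[[colorVar]],
                                         size = .data$.size)) +
        ggplot2::geom_point(alpha = 0.85) +
        ggplot2::scale_size_identity() +
        ggplot2::facet_wrap(facetVar) +
        ggplot2::labs(x = "Risk allele frequency", y = "Odds ratio",
                      color = colorVar) +
        ggplot2::guides(size = "none") +
        ggplot2::theme_bw()
    if (logOR) p <- p + ggplot2::scale_y_log10()
    if (is.null(path)) return(p)
    dev <- switch(format, svg = grDevices::svg, png = function(f, ...)
        grDevices::png(f, ..., units = "in", res = 150))
    dev(path, width = width, height = height)
    on.exit(grDevices::dev.off())
    print(p)
    invisible(p)
}
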