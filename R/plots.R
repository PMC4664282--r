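#' Plot a genome scan
#'
#' LOD profile along the genome, faceted by chromosome, with an optional
#' horizontal line at the genomewide significance threshold.
#'
#' @param object A `qtl_scan` tibble.
#' @param threshold Optional LOD threshold (number or `perm_null`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot qtl_scan
autoplot.qtl_scan <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$cm, y = .data$lod)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
      scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "Genetic position (cM)", y = "LOD") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    thr <- if (inherits(threshold, "perm_null")) threshold$threshold else threshold
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dotted")
  }
  p
}

#' Plot founder haplotype means at a QTL
#'
#' Bar chart of founder means with 1-SD error bars and per-founder line
#' counts; founders below the reporting rule (`reported = FALSE`) are
#' omitted.
#'
#' @param effects Tibble from [founder_effects()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_founder_effects <- function(effects, ...) {
  dat <- dplyr::filter(effects, .data$reported)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$founder, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.25) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n, y = 0),
      vjust = -0.5, size = 3) +
    ggplot2::labs(x = "Founder haplotype", y = "Mean phenotype (h)") +
    ggplot2::theme_minimal()
}

#' Plot the permutation null distribution
#'
#' @param object A `perm_null` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot perm_null
autoplot.perm_null <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$max_lod)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "Genomewide maximum LOD per permutation", y = "Count") +
    ggplot2::theme_minimal()
}
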