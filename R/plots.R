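#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_histogram
#'   geom_vline geom_tile scale_fill_viridis_c labs theme_minimal
#'   coord_equal
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Plot PCA scores
#'
#' @param object A `geno_pca` from [pca_genotypes()].
#' @param colour_by Optional tibble `sample_id`, `group` used to colour
#'   points.
#' @param pcs Which two PCs to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.geno_pca <- function(object, colour_by = NULL, pcs = c(1, 2), ...) {
  df <- object$scores
  xy <- paste0("PC", pcs)
  if (!is.null(colour_by)) {
    df <- dplyr::left_join(df, colour_by, by = "sample_id")
    p <- ggplot(df, aes(
      .data[[xy[1]]], .data[[xy[2]]],
      colour = .data$group
    ))
  } else {
    p <- ggplot(df, aes(.data[[xy[1]]], .data[[xy[2]]]))
  }
  p + geom_point(alpha = 0.7, size = 1) +
    labs(
      x = sprintf("%s (%.1f%%)", xy[1], 100 * object$var_explained[pcs[1]]),
      y = sprintf("%s (%.1f%%)", xy[2], 100 * object$var_explained[pcs[2]])
    ) +
    theme_minimal()
}

#' Plot an enrichment log2-ratio distribution
#'
#' Histogram of log2 AF ratios with the observed-record median marked;
#' sentinel records pile up at the left edge.
#'
#' @param records Tibble from [enrichment_records()].
#' @param ratio_min Enrichment threshold to mark.
#' @return A ggplot.
#' @export
plot_enrichment <- function(records, ratio_min = 2) {
  med <- median(records$log2_ratio[records$observed])
  ggplot(records, aes(.data$log2_ratio)) +
    geom_histogram(bins = 60, fill = "grey35") +
    geom_vline(xintercept = med, colour = "red", linetype = "dashed") +
    geom_vline(xintercept = ratio_min, colour = "blue", linetype = "dotted") +
    labs(
      x = "log2 allele-frequency ratio",
      y = "variants",
      title = sprintf("median (observed) = %.2f", med)
    ) +
    theme_minimal()
}

#' Heatmap of median pairwise IBD sharing
#'
#' @param object A `pop_sharing` from [population_median_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pop_sharing <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(.data$pop_a, .data$pop_b, fill = .data$median_cm)) +
    geom_tile() +
    scale_fill_viridis_c(name = "median cM") +
    coord_equal() +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Manhattan-style plot of GWAS results
#'
#' @param results A `gwas_result` tibble from [run_gwas()].
#' @param threshold Significance line to draw.
#' @return A ggplot, faceted by phenotype.
#' @export
plot_gwas <- function(results, threshold = 5e-8) {
  ggplot(results, aes(.data$pos, -log10(.data$p))) +
    geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(
      yintercept = -log10(threshold),
      colour = "red", linetype = "dashed"
    ) +
    ggplot2::facet_wrap(~phenotype) +
    labs(x = "position (bp)", y = "-log10 p") +
    theme_minimal()
}
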