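# ggplot2 displays for the main result types.

#' Plot a bootstrap enrichment result
#'
#' Null density of the bootstrapped overlap proportions with the observed
#' proportion as a dashed vertical line.
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  null <- tibble::tibble(proportion = attr(object, "null_sample"))
  ggplot2::ggplot(null, ggplot2::aes(x = .data$proportion)) +
    ggplot2::geom_density(fill = "grey80", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(
      title = paste(object$spot_set, "vs", object$annotation),
      subtitle = sprintf("observed %.2f%% | null mean %.2f%% | p = %.3g",
                         100 * object$observed, 100 * object$null_mean,
                         object$p_enrich),
      x = "overlap proportion (bootstrap null)", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a damage-centred nucleotide frequency matrix
#'
#' Per-position base frequencies around the damage dinucleotide
#' (positions 0/+1), one panel per strand.
#'
#' @param object A `freq_matrix` from [nucleotide_frequency()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.freq_matrix <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$position, y = .data$freq,
                               colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~strand) +
    ggplot2::geom_vline(xintercept = c(0, 1), linetype = "dotted") +
    ggplot2::labs(x = "position relative to damage site",
                  y = "nucleotide frequency", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a PCA repair trajectory
#'
#' Samples in PC1/PC2 space, coloured by time point and connected in
#' temporal order.
#'
#' @param object A `repair_pca` from [pca_trajectory()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.repair_pca <- function(object, ...) {
  ve <- attr(object, "var_explained")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if ("time_point" %in% names(object)) {
    ord <- dplyr::arrange(object, .data$time_rank)
    p <- p +
      ggplot2::geom_path(data = ord, colour = "grey70") +
      ggplot2::geom_point(ggplot2::aes(colour = .data$time_point), size = 3)
  } else {
    p <- p + ggplot2::geom_point(size = 3)
  }
  p + ggplot2::labs(
    x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
    y = sprintf("PC2 (%.1f%%)", 100 * ve[min(2, length(ve))]),
    colour = "time point") +
    ggplot2::theme_minimal()
}

#' Distribution of per-bin read counts across samples
#'
#' Log-count heat map of the number of bins at each read depth, one row
#' per sample — early-repair hotspots appear as a long right tail in the
#' early time points.
#'
#' @param x A [bin_count_matrix()].
#' @param max_count Right-censor depth for display.
#' @return A ggplot.
#' @export
plot_bin_count_distribution <- function(x, max_count = 30L) {
  stopifnot(inherits(x, "bin_counts"))
  long <- tidy(x) |>
    dplyr::filter(!.data$masked) |>
    dplyr::mutate(depth = pmin(.data$count, max_count)) |>
    dplyr::count(.data$sample, .data$depth, name = "n_bins")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$depth, y = .data$sample,
                                     fill = log10(.data$n_bins + 1))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10 bins") +
    ggplot2::labs(x = "reads per bin", y = NULL) +
    ggplot2::theme_minimal()
}
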