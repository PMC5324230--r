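#' Plot the inhibition distribution with fitted mixture components
#'
#' Histogram of case inhibition percentages overlaid with the scaled
#' density of each fitted Gaussian component (when the mixture fit
#' succeeded) and the assignment threshold region.
#'
#' @param object A `gcm_subgroups` object.
#' @param data Optional tibble with `inhibition_pct` to plot instead of
#'   reconstructing from the assignments.
#' @param bins Histogram bins. Default 15.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.gcm_subgroups <- function(object, data = NULL, bins = 15, ...) {
  df <- data %||% object$assignments
  if (!"inhibition_pct" %in% names(df)) {
    abort("supply `data` with an inhibition_pct column",
          class = "gcm_validation_error")
  }
  p <- ggplot(df, aes(x = .data$inhibition_pct)) +
    geom_histogram(aes(y = after_stat(density)), bins = bins,
                   fill = "grey80", colour = "grey40") +
    labs(x = "Inhibition (%)", y = "Density",
         title = "Dexamethasone suppression: case inhibition") +
    theme_minimal()
  if (!is.null(object$components)) {
    grid <- seq(min(df$inhibition_pct) - 10, max(df$inhibition_pct) + 10,
                length.out = 300)
    dens <- object$components |>
      rowwise() |>
      reframe(x = grid,
              density = .data$weight * dnorm(grid, .data$mean, .data$sd),
              component = .data$component)
    p <- p + geom_line(data = dens,
                       aes(x = .data$x, y = .data$density,
                           colour = .data$component))
  }
  p
}

#' Plot RAND-36 principal component scores
#'
#' Scatter of the first two principal components, coloured by clinical
#' group when available.
#'
#' @param object A `gcm_pca` object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.gcm_pca <- function(object, ...) {
  df <- object$scores
  ve <- object$variance_explained
  p <- ggplot(df, aes(x = .data$PC1, y = .data$PC2)) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * ve[2]),
         title = "RAND-36 principal components") +
    theme_minimal()
  if ("group" %in% names(df)) {
    p + geom_point(aes(colour = .data$group), size = 2)
  } else {
    p + geom_point(size = 2)
  }
}

#' Plot three-comparison overlap counts
#'
#' Bar chart of the seven disjoint Venn region counts of the
#' hypersensitive/typical/control comparisons.
#'
#' @param object A `gcm_venn` object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.gcm_venn <- function(object, ...) {
  ggplot(object$regions,
         aes(x = stats::reorder(.data$region, -.data$count),
             y = .data$count)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "Differentially methylated sites",
         title = "Overlap of subgroup comparisons") +
    theme_minimal()
}

#' Volcano-style plot of differential methylation
#'
#' Mean beta-difference against -log10 nominal p, with the significance
#' calls highlighted.
#'
#' @param dms DM records from [diff_methylation()].
#' @param diff_min Effect-size gate to draw. Default 0.05.
#' @return A ggplot object.
#' @export
plot_volcano <- function(dms, diff_min = 0.05) {
  ggplot(dms, aes(x = .data$beta_diff,
                  y = -log10(pmax(.data$p_wilcoxon, 1e-300)),
                  colour = .data$significant)) +
    geom_point(alpha = 0.5, size = 0.8) +
    geom_vline(xintercept = c(-diff_min, diff_min), linetype = "dashed") +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    labs(x = "Mean beta-difference", y = "-log10 p (Wilcoxon)",
         colour = "Significant") +
    theme_minimal()
}
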