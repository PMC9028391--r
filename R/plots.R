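# ggplot2 visualizations for the main result types.

#' Plot a pixel-by-pixel class map
#'
#' The field's usual color convention: HP green, HT yellow, PTC red;
#' unclassified raster positions are left blank.
#'
#' @param sample An `msi_nodule`.
#' @param calls Tibble with `x`, `y`, `class_call` (e.g. pixel rows of
#'   [classify_units()]).
#' @return A ggplot object.
#' @export
plot_pixel_class_map <- function(sample, calls) {
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$class_call)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = roi_class_colors(), name = NULL) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(xlim = c(0.5, max(sample$coords$x) + 0.5)) +
    ggplot2::labs(title = sample$sample_id, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Score plot of an exploratory PCA
#'
#' @param object An `msi_pca` object.
#' @param group Optional grouping vector (e.g. truth labels) aligned with
#'   the score rows.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.msi_pca <- function(object, group = NULL, ...) {
  df <- object$scores
  df$group <- group %||% "sample"
  ev <- pct_round(100 * object$explained_variance)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   color = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = paste0("PC1 (", ev[1], "%)"),
                  y = paste0("PC2 (", ev[2], "%)"), color = NULL) +
    ggplot2::theme_minimal()
}

#' Malignant-pixel-fraction plot with the triage bands
#'
#' One point per nodule ordered by malignant pixel fraction; the horizontal
#' lines mark the low and high cutoffs bounding the gray zone.
#'
#' @param object An `msi_diagnosis` tibble.
#' @param thresholds An [diagnosis_thresholds()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.msi_diagnosis <- function(object, thresholds = diagnosis_thresholds(),
                                   ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$malignant_pixel_fraction), ]
  df$rank <- rank(df$malignant_pixel_fraction, ties.method = "first")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                   y = .data$malignant_pixel_fraction,
                                   color = .data$call_three_level)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = thresholds$pixel_cutoff_low,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = thresholds$pixel_cutoff_high,
                        linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(benign = "#2CA02C",
                                           gray = "#8C8C8C",
                                           malignant = "#CC1F1F"),
                                name = NULL) +
    ggplot2::labs(x = "nodule (ranked)", y = "malignant pixel fraction") +
    ggplot2::theme_minimal()
}
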