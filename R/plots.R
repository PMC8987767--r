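# ggplot2 autoplot methods for the package's result objects.

#' Plot a calibration sample with its percentile threshold
#'
#' Histogram of the measured nucleus areas with the selected percentile
#' threshold marked as a red vertical line.
#'
#' @param object A `cyto_calibration` from [percentile_threshold()].
#' @param binwidth Histogram bin width in µm² (default 5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyto_calibration <- function(object, binwidth = 5, ...) {
  df <- tibble(area = object$areas)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$area)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey70",
                            colour = "grey35") +
    ggplot2::geom_vline(xintercept = object$threshold, colour = "red",
                        linewidth = 0.8) +
    ggplot2::labs(
      x = expression("nucleus area (" * mu * m^2 * ")"),
      y = "frequency",
      title = sprintf("%g-th percentile threshold: %.1f µm²",
                      object$percentile_q, object$threshold)) +
    ggplot2::theme_minimal()
}

#' Plot a smear composition profile
#'
#' Bar chart of the per-class cell proportions.
#'
#' @param object A `cyto_smear_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyto_smear_profile <- function(object, ...) {
  df <- tidy(object)
  df$class <- factor(df$class, levels = CELL_CLASSES)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%",
                                                             100 * x)) +
    ggplot2::labs(x = NULL, y = "proportion of cells") +
    ggplot2::theme_minimal()
}

#' Plot a rendered smear image
#'
#' Grayscale raster of the synthetic smear; with `show_mask = TRUE` the
#' ground-truth cell regions are tinted by mask id.
#'
#' @param object A `cyto_smear_image`.
#' @param show_mask Overlay the ground-truth mask (default `FALSE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyto_smear_image <- function(object, show_mask = FALSE, ...) {
  img <- object$image
  df <- tibble(
    x = rep(seq_len(ncol(img)), each = nrow(img)) * object$microns_per_pixel,
    y = rep(seq_len(nrow(img)), times = ncol(img)) * object$microns_per_pixel,
    value = as.vector(img),
    mask = as.vector(object$mask))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = expression(mu * m), y = expression(mu * m)) +
    ggplot2::theme_minimal()
  if (show_mask) {
    p <- p + ggplot2::geom_raster(
      data = df[df$mask > 0, ],
      ggplot2::aes(alpha = 0.3), fill = "red", show.legend = FALSE)
  }
  p
}

#' Plot per-subject agreement for a Fleiss' kappa result
#'
#' Dot plot of the per-subject agreement values with the overall mean and
#' chance-expected agreement marked.
#'
#' @param object A `cyto_fleiss_kappa`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyto_fleiss_kappa <- function(object, ...) {
  df <- tidy(object)
  df$subject <- factor(df$subject, levels = df$subject)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject,
                                   y = .data$agreement)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$p_bar, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$p_e, colour = "red",
                        linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "subject", y = "per-subject agreement",
                  title = sprintf("kappa = %.3f (%s)", object$kappa,
                                  object$band)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
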