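#' Plot a phasor field as a 2-D density over the unit disk
#'
#' @param object A [phasor_field()].
#' @param bins Hexbin-equivalent resolution passed to
#'   [ggplot2::geom_bin2d()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.phasor_field <- function(object, bins = 128, ...) {
  df <- dplyr::filter(as_tibble(object), .data$valid)
  angle <- seq(0, 2 * pi, length.out = 361)
  circle <- tibble::tibble(G = cos(angle), S = sin(angle))
  ggplot2::ggplot(df, ggplot2::aes(.data$G, .data$S)) +
    ggplot2::geom_bin2d(bins = bins) +
    ggplot2::geom_path(data = circle, linetype = "dashed",
                       color = "grey50") +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "G", y = "S", fill = "pixels",
                  title = sprintf("Spectral phasor (harmonic %d)",
                                  object$harmonic)) +
    ggplot2::theme_minimal()
}

#' Plot the per-pixel mean-lifetime map of a FLIM fit
#'
#' @param object A [fit_image()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.flim_image <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$tau_mean)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "turbo", na.value = "black") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "tau_mean (ns)") +
    ggplot2::theme_minimal()
}

#' Bar-and-error plot of group statistics with significance stars
#'
#' Group means with SEM error bars, annotated with the ANOVA p-value; the
#' pairwise Tukey stars live in `tidy(object)`.
#'
#' @param object A [group_stats()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.group_stats <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(.data$group, .data$mean)) +
    ggplot2::geom_col(fill = "grey70", color = "black", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem), width = 0.2) +
    ggplot2::labs(
      y = "mean ± SEM",
      subtitle = sprintf("one-way ANOVA F = %.3g, p = %.2g (%s)",
                         object$anova$statistic, object$anova$p.value,
                         significance_stars(object$anova$p.value))) +
    ggplot2::theme_classic()
}

#' Plot a region spectrum
#'
#' @param object Tibble from [extract_region_spectrum()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_region_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$center_nm, .data$counts)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "emission wavelength (nm)",
                  y = "integrated counts") +
    ggplot2::theme_classic()
}

#' @importFrom rlang .data
NULL
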