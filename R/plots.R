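# ggplot2 views of the result types.

#' Plot a processed spectrum
#'
#' Raw/processed intensity trace with the fitted baseline overlaid when
#' present.
#'
#' @param spec Spectrum tibble (`intensity_norm` preferred).
#' @return A ggplot.
#' @export
plot_spectrum <- function(spec) {
  ycol <- if ("intensity_norm" %in% names(spec)) "intensity_norm"
          else "intensity_au"
  p <- ggplot2::ggplot(spec, ggplot2::aes(.data$wavenumber_cm1,
                                          .data[[ycol]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "wavenumber (1/cm)", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
  if ("baseline_au" %in% names(spec) && ycol == "intensity_au")
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$baseline_au),
                                colour = "red", linetype = 2)
  p
}

#' @export
autoplot.fiber_network <- function(object, ...) {
  mask_df <- which(object$mask, arr.ind = TRUE)
  sk_df <- which(object$skeleton, arr.ind = TRUE)
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = as.data.frame(mask_df),
                         ggplot2::aes(.data$col, -.data$row),
                         fill = "grey80") +
    ggplot2::geom_raster(data = as.data.frame(sk_df),
                         ggplot2::aes(.data$col, -.data$row),
                         fill = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_void()
  if (nrow(object$nodes) > 0)
    p <- p + ggplot2::geom_point(data = object$nodes,
                                 ggplot2::aes(.data$col, -.data$row),
                                 colour = "red", size = 1)
  p
}

#' @export
autoplot.hertz_fit <- function(object, ...) {
  d <- object$data
  if (object$ok) {
    d$fit_nN <- object$baseline_nN +
      hertz_force(d$displacement_nm - object$contact_point_nm,
                  object$E_pa, object$tip_radius_um, object$poisson_ratio)
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$displacement_nm,
                                       .data$force_nN)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::labs(x = "displacement (nm)", y = "force (nN)") +
    ggplot2::theme_minimal()
  if (object$ok)
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$fit_nN),
                                colour = "red")
  p
}

#' @export
autoplot.stiffness_distribution <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(.data$bin_mid_pa, .data$count)) +
    ggplot2::geom_col(width = object$bin_width_pa * 0.9,
                      fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$modes_pa, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "Young's modulus (Pa)", y = "curves") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.raman_pca <- function(object, ...) {
  if (object$zero_variance)
    stop_ecm("Cannot plot a zero-variance PCA.", "degenerate_input")
  ggplot2::ggplot(object$scores, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)",
                  100 * object$explained_variance_fraction[1]),
      y = if (length(object$explained_variance_fraction) > 1)
        sprintf("PC2 (%.1f%%)",
                100 * object$explained_variance_fraction[2]) else "PC2") +
    ggplot2::theme_minimal()
}
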