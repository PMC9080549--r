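#' Plot per-subject spectral signatures
#'
#' @param signatures Tibble from [roi_signature()] / [smooth_signature()].
#' @return A ggplot object: reflectance vs wavelength, one line per subject.
#' @export
plot_signatures <- function(signatures) {
  ggplot2::ggplot(signatures,
                  ggplot2::aes(x = .data$wavelength_nm,
                               y = .data$reflectance_pct,
                               colour = .data$subject_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "diffuse reflectance (%)",
                  colour = "subject") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot optimum_band
#' @export
autoplot.optimum_band <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$wavelength_nm, y = .data$criterion)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$wavelength, linetype = 2) +
    ggplot2::labs(x = "wavelength (nm)", y = "|Pearson r| vs SpO2",
                  title = sprintf("optimum band %.1f nm", object$wavelength)) +
    ggplot2::theme_minimal()
}

#' Plot a band image as a raster
#'
#' @param img A [band_image()].
#' @return A ggplot raster of the image.
#' @export
plot_band_image <- function(img) {
  stopifnot(inherits(img, "band_image"))
  df <- tibble::tibble(
    row = rep(seq_len(nrow(img$values)), ncol(img$values)),
    col = rep(seq_len(ncol(img$values)), each = nrow(img$values)),
    value = as.vector(img$values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s @ %.1f nm", img$kind, img$wavelength),
                  fill = NULL) +
    ggplot2::theme_void()
}

#' @method autoplot cohort_analysis
#' @export
autoplot.cohort_analysis <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(x = .data$spo2_oximeter, y = .data$spo2_est)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "pulse oximeter SpO2 (%)", y = "image-estimated SpO2 (%)") +
    ggplot2::theme_minimal()
}
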