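#' @export
tidy.fs_image <- function(x, ...) {
  tibble(x_mm = rep(x$x, times = length(x$y)),
         y_mm = rep(x$y, each = length(x$x)),
         radiance = as.vector(x$values))
}

#' @export
tidy.fs_scan <- function(x, ...) {
  tibble(x_mm = rep(x$sx, times = length(x$sy)),
         y_mm = rep(x$sy, each = length(x$sx)),
         reading = as.vector(x$values))
}

#' @export
tidy.fs_coupling <- function(x, ...) {
  tibble(mode = x$mode, lambda_ex_nm = x$lambda_ex, lambda_em_nm = x$lambda_em,
         factor = x$value)
}

#' Plot methods
#'
#' `autoplot()` methods render the package's result objects with ggplot2:
#' surface images and scan images as rasters, profiles as lines (with the
#' half-maximum level when a resolution object is supplied), and sweep
#' tables as radiance/resolution curves.
#'
#' @param object A `fluorscan` result object.
#' @param trans Transformation for the fill scale of image plots (e.g.
#'   `"log10"`); default identity.
#' @param ... Unused.
#' @return A ggplot object.
#' @name fluorscan-autoplot
NULL

#' @rdname fluorscan-autoplot
#' @export
autoplot.fs_image <- function(object, trans = "identity", ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$x_mm, .data$y_mm,
                                  fill = .data$radiance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans,
                                  name = "radiance\n(photons/s/mm²/sr)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("Surface radiance, %s face", object$face)) +
    ggplot2::theme_minimal()
}

#' @rdname fluorscan-autoplot
#' @export
autoplot.fs_scan <- function(object, trans = "identity", ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$x_mm, .data$y_mm,
                                  fill = .data$reading)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans,
                                  name = "reading\n(photons/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "scan x (mm)", y = "scan y (mm)",
                  title = sprintf("Scan image, %s mode (%s method)",
                                  object$mode, object$method)) +
    ggplot2::theme_minimal()
}

#' @rdname fluorscan-autoplot
#' @export
autoplot.fs_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$coord, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = sprintf("%s (mm)", attr(object, "along")),
                  y = "signal") +
    ggplot2::theme_minimal()
}

#' @rdname fluorscan-autoplot
#' @export
autoplot.fs_resolution <- function(object, ...) {
  p <- autoplot(object$profile)
  p + ggplot2::geom_vline(xintercept = object$peaks, linetype = 3) +
    ggplot2::labs(title = sprintf("Per-target FWHM %.2f / %.2f mm (resolution %.2f mm)",
                                  object$fwhm[1], object$fwhm[2],
                                  object$resolution))
}

#' @rdname fluorscan-autoplot
#' @export
autoplot.fs_sweep <- function(object, ...) {
  swept <- attr(object, "swept")
  xlab <- if (identical(swept, "z_mm")) "target depth z (mm)"
          else "emission wavelength (nm)"
  d <- tibble(x = object[[swept]],
              radiance = object$mean_radiance,
              resolution = object$resolution_mm)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$radiance)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = xlab, y = "mean detected radiance (log scale)",
                  title = sprintf("%s, %s mode", object$instrument[1],
                                  object$mode[1])) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
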