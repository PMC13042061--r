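# Plotting and broom-style accessors for the fitted/derived objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-lenslet translation-curve fits
#'
#' @param x a `translation_model`.
#' @param ... unused.
#' @return tibble of per-lenslet slopes, intercepts and residual RMS.
#' @method tidy translation_model
#' @export
tidy.translation_model <- function(x, ...) x$coefficients

#' @rdname tidy.translation_model
#' @method glance translation_model
#' @export
glance.translation_model <- function(x, ...) {
  tibble::tibble(n_lenslets = nrow(x$coefficients),
                 n_depths = length(unique(x$knots$z_um)),
                 z_min_um = x$z_range[1], z_max_um = x$z_range[2],
                 rms_px = sqrt(mean(c(x$coefficients$rms_x^2,
                                      x$coefficients$rms_y^2))))
}

#' @rdname tidy.translation_model
#' @method tidy depth_estimate
#' @export
tidy.depth_estimate <- function(x, ...) x$curve

#' @rdname tidy.translation_model
#' @method glance depth_estimate
#' @export
glance.depth_estimate <- function(x, ...) {
  tibble::tibble(z_est_um = x$z_est_um, n_layers = nrow(x$curve))
}

#' Plot an axial response curve
#'
#' @param object an `axial_response`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot axial_response
#' @export
autoplot.axial_response <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z_um, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "z (µm)", y = "normalized response",
                  subtitle = attr(object, "criterion")) +
    ggplot2::theme_minimal()
}

#' Plot translation curves (knots and interpolants)
#'
#' @param object a `translation_model`.
#' @param ... unused.
#' @return a ggplot of shift magnitude versus depth per edge lenslet.
#' @method autoplot translation_model
#' @export
autoplot.translation_model <- function(object, ...) {
  kn <- object$knots
  kn$shift_px <- sqrt(kn$dx_px^2 + kn$dy_px^2)
  kn$lens <- factor(kn$lens_id)
  ggplot2::ggplot(kn, ggplot2::aes(x = .data$z_um, y = .data$shift_px,
                                   colour = .data$lens)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "depth (µm)", y = "shift magnitude (px)",
                  colour = "lenslet") +
    ggplot2::theme_minimal()
}

#' Plot a depth-from-focus score curve
#'
#' @param object a `depth_estimate`.
#' @param ... unused.
#' @return a ggplot with the interpolated peak marked.
#' @method autoplot depth_estimate
#' @export
autoplot.depth_estimate <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$z_um, y = .data$score)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$z_est_um, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "refocus depth (µm)", y = "focus score") +
    ggplot2::theme_minimal()
}

#' Plot functional-zone diameters versus depth
#'
#' @param extents a [zone_extents()] tibble.
#' @return a ggplot.
#' @export
plot_zone_extents <- function(extents) {
  df <- rbind(
    data.frame(z_um = extents$z_um, diameter_um = extents$foveated_um, zone = "foveated"),
    data.frame(z_um = extents$z_um, diameter_um = extents$blend_um, zone = "blend"),
    data.frame(z_um = extents$z_um, diameter_um = extents$peripheral_um, zone = "peripheral"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z_um, y = .data$diameter_um,
                                   colour = .data$zone)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth (µm)", y = "zone diameter (µm)") +
    ggplot2::theme_minimal()
}
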