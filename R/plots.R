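# ggplot2 visualisations of the result types.

#' Plot a DMF curve
#'
#' DMF versus tissue depth with 1-sigma error bars.
#'
#' @param object A `dmf_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dmf_curve <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$tissue_depth_cm, y = .data$dmf,
                colour = .data$plan)) +
    geom_pointrange(aes(ymin = .data$dmf * (1 - .data$rse),
                        ymax = .data$dmf * (1 + .data$rse))) +
    geom_line() +
    labs(x = "tissue depth beyond reference point (cm)",
         y = "dose modification factor",
         title = sprintf("DMF vs backscatter depth (%s phantom)",
                         d$phantom[1])) +
    theme_minimal()
}

#' Plot several DMF curves together
#'
#' @param ... `dmf_curve` objects.
#' @return A ggplot object.
#' @export
plot_dmf_curves <- function(...) {
  d <- bind_rows(lapply(list(...), tidy))
  ggplot(d, aes(x = .data$tissue_depth_cm, y = .data$dmf,
                colour = .data$phantom, linetype = .data$plan)) +
    geom_pointrange(aes(ymin = .data$dmf * (1 - .data$rse),
                        ymax = .data$dmf * (1 + .data$rse))) +
    geom_line() +
    labs(x = "tissue depth beyond reference point (cm)",
         y = "dose modification factor") +
    theme_minimal()
}

#' Plot a dose kernel
#'
#' Relative dose rate of a single dwell on the (r, theta) grid, log colour
#' scale.
#'
#' @param object A `dose_kernel`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dose_kernel <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$theta_deg, y = .data$r_cm, fill = log10(.data$value))) +
    geom_raster() +
    scale_y_log10() +
    labs(x = "polar angle (deg)", y = "r (cm)",
         fill = "log10 relative dose",
         title = "single-dwell dose kernel in water") +
    theme_minimal()
}

#' Plot a dose-grid slice
#'
#' Central transverse (x-y) slice of the 3-D dose grid in percent of
#' prescription, with the balloon outline.
#'
#' @param object A `dose_grid`.
#' @param z Slice position, cm (default 0, the central plane).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dose_grid <- function(object, z = 0, ...) {
  ax <- grid_axis(object)
  k <- which.min(abs(ax - z))
  d <- tidyr::expand_grid(y = ax, x = ax)[, c("x", "y")]
  d$dose <- as.vector(object$values[, , k])
  d$pct <- pmin(100 * d$dose / object$prescription, 400)
  circ <- tibble(t = seq(0, 2 * pi, length.out = 181),
                 x = object$balloon_radius * cos(t),
                 y = object$balloon_radius * sin(t))
  ggplot(d, aes(.data$x, .data$y, fill = .data$pct)) +
    geom_raster() +
    geom_path(data = circ, aes(.data$x, .data$y), inherit.aes = FALSE,
              colour = "white") +
    coord_equal(xlim = c(-8, 8), ylim = c(-8, 8)) +
    labs(x = "x (cm)", y = "y (cm)", fill = "% of prescription",
         title = sprintf("dose at z = %.2f cm", ax[k])) +
    theme_minimal()
}
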