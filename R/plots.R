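#' Sensor topography plot
#'
#' Schematic head-map of a per-channel quantity: sensors are drawn at their
#' layout positions on the unit disc (nose up), colored by value; frontal
#' channels are ringed in bold.
#'
#' @param layout a [make_layout()] result.
#' @param values numeric per-channel vector.
#' @param main plot title.
#' @param palette color ramp function (default blue-white-red).
#' @return Invisibly `NULL`; draws on the current device.
#' @export
plot_topography <- function(layout, values, main = "",
                            palette = grDevices::colorRampPalette(
                              c("#2166AC", "#F7F7F7", "#B2182B"))) {
  stopifnot(inherits(layout, "sensor_layout"),
            length(values) == nrow(layout$positions))
  rng <- range(values, finite = TRUE)
  idx <- if (diff(rng) == 0) rep(1L, length(values)) else
    pmax(1L, pmin(100L, 1L + floor(99 * (values - rng[1]) / diff(rng))))
  cols <- palette(100)[idx]
  graphics::plot(NA, xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.35),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th))
  graphics::lines(c(-0.1, 0, 0.1), c(0.995, 1.12, 0.995))  # nose
  graphics::points(layout$positions[, 1], layout$positions[, 2],
                   pch = 21, bg = cols, cex = 1.1,
                   lwd = ifelse(layout$frontal_mask, 2.2, 0.6))
  invisible(NULL)
}
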