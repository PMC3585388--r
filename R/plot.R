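#' Polar plot of a reconstructed retina
#'
#' Draws the reconstructed mesh in the azimuthal equidistant projection
#' centred on the retinal pole: mesh edges in grey, the retinal rim in
#' black, stitched cut lines in cyan, and any mapped data sets as
#' points.
#'
#' @param x A `retina_reconstruction`.
#' @param datasets Logical; map and draw the outline's attached data sets.
#' @param ... Further arguments passed to `plot`.
#' @export
plot.retina_reconstruction <- function(x, datasets = TRUE, ...) {
  phi0 <- as.numeric(x$rim_angle)
  sph <- x$class_sphere
  xy <- project_azimuthal_equidistant(sph)
  graphics::plot(NA, xlim = c(-phi0, phi0) * 1.05,
                 ylim = c(-phi0, phi0) * 1.05, asp = 1,
                 xlab = "colatitude (deg)", ylab = "",
                 main = sprintf("reconstructed retina (E_L = %.3f)", x$E_L),
                 ...)
  e <- x$sys$edges
  graphics::segments(xy[e[, 1], 1], xy[e[, 1], 2],
                     xy[e[, 2], 1], xy[e[, 2], 2], col = "grey80")
  th <- seq(0, 2 * pi, length.out = 181)
  graphics::lines(phi0 * cos(th), phi0 * sin(th), lwd = 2)
  ## stitched cuts: edges between classes holding corresponded vertices
  if (nrow(x$mesh$correspondences)) {
    cut_cls <- unique(x$sys$cls[as.vector(x$mesh$correspondences)])
    on_cut <- e[, 1] %in% cut_cls & e[, 2] %in% cut_cls
    graphics::segments(xy[e[on_cut, 1], 1], xy[e[on_cut, 1], 2],
                       xy[e[on_cut, 2], 1], xy[e[on_cut, 2], 2],
                       col = "cyan3", lwd = 1.5)
  }
  if (datasets && length(x$outline$datasets)) {
    cols <- grDevices::hcl.colors(max(3, length(x$outline$datasets)),
                                  "Dark 3")
    for (i in seq_along(x$outline$datasets)) {
      d <- x$outline$datasets[[i]]
      if (!nrow(d)) next
      mp <- map_to_sphere(x, d)
      pxy <- project_azimuthal_equidistant(mp)
      graphics::points(pxy, col = cols[i], pch = 16, cex = 0.6)
    }
  }
  invisible(x)
}
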