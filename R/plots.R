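# Base-graphics visualization: ROI overlays, identity-line scatter,
# binned CSA distribution.

#' Plot a segmentation result
#'
#' Draws the fiber outlines, optionally over the grayscale image, the way
#' detected ROIs are superimposed for visual checking. Automatic fibers are
#' drawn in yellow, manual additions in green.
#'
#' @param x a `segmentation_result`.
#' @param image optional [muscle_image()] backdrop.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.segmentation_result <- function(x, image = NULL, ...) {
  W <- x$image_size[1]; H <- x$image_size[2]
  op <- par(mar = c(2, 2, 2, 1))
  on.exit(par(op))
  plot(NA, xlim = c(0, W), ylim = c(H, 0), asp = 1, xlab = "", ylab = "",
       main = sprintf("%s: %d fibers", x$image_name, length(x$rois)), ...)
  if (!is.null(image)) {
    maxval <- 2^image$bit_depth - 1
    rast <- grDevices::as.raster(image$pixels / maxval)
    graphics::rasterImage(rast, 0, H, W, 0)
  }
  for (roi in x$rois) {
    col <- if (roi$origin == "manual") "green3" else "yellow"
    polygon(roi$polygon[, 1], roi$polygon[, 2], border = col, lwd = 1)
  }
  invisible(x)
}

#' Identity-line agreement scatter of two CSA series
#'
#' Per-image mean CSA of method B against method A, with the identity line
#' (dotted) and the least-squares fit.
#'
#' @param a,b numeric vectors of per-image mean CSA (um^2).
#' @param xlab,ylab axis labels.
#' @param ... passed to [graphics::plot()].
#' @return The [correlation_identity()] statistics, invisibly.
#' @export
plot_identity <- function(a, b, xlab = "method A mean CSA (um^2)",
                          ylab = "method B mean CSA (um^2)", ...) {
  stats <- correlation_identity(a, b)
  lim <- range(c(a, b))
  plot(a, b, xlim = lim, ylim = lim, xlab = xlab, ylab = ylab,
       pch = 19, ...)
  abline(0, 1, lty = 3)
  abline(stats$intercept, stats$slope, col = "red3")
  legend("topleft", bty = "n",
         legend = sprintf("R² = %.4f  slope = %.3f", stats$r_squared,
                          stats$slope))
  invisible(stats)
}

#' Barplot of a binned CSA distribution
#'
#' @param result a `segmentation_result` or numeric vector of areas.
#' @param spec a [distribution_spec()].
#' @param ... passed to [graphics::barplot()].
#' @return The distribution data.frame, invisibly.
#' @export
plot_csa_distribution <- function(result, spec = distribution_spec(), ...) {
  d <- csa_distribution(result, spec)
  barplot(d$fraction, names.arg = d$bin, las = 2,
          ylab = "fraction of fibers", ...)
  invisible(d)
}
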