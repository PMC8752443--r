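## Minimal plotting layer (base graphics): slice clone maps and hotspot
## distance distributions.

#' Plot a tumour slice coloured by clone
#'
#' @param slice a [TumourSlice-class].
#' @param drawContour overlay the smoothed contour.
#' @param ... passed to [graphics::image()].
#' @return NULL, invisibly.
#' @export
plotSlice <- function(slice, drawContour = TRUE, ...) {
  lab <- matrix(NA_integer_, slice@dims[1], slice@dims[2])
  lab[cbind(slice@sites$x, slice@sites$y)] <- slice@sites$clone_id
  graphics::image(seq_len(slice@dims[1]), seq_len(slice@dims[2]), lab,
                  xlab = "x (mm)", ylab = "y (mm)", useRaster = TRUE, ...)
  if (drawContour && nrow(slice@contourSmooth) > 2L) {
    P <- rbind(slice@contourSmooth, slice@contourSmooth[1, , drop = FALSE])
    graphics::lines(P[, 1], P[, 2], lwd = 2)
  }
  invisible(NULL)
}

#' Plot the cumulative distribution of hotspot distances with its fit
#'
#' @param d normalised centre distances.
#' @param fit optional [PowerLawFit-class] whose median bootstrap exponent
#'   is drawn as the fitted curve; the null model d^2 is always shown.
#' @return NULL, invisibly.
#' @export
plotHotspotCDF <- function(d, fit = NULL) {
  ds <- sort(d)
  P <- seq_along(ds) / length(ds)
  graphics::plot(ds, P, type = "s", xlab = "normalised distance d",
                 ylab = "P(D <= d)", xlim = c(0, 1), ylim = c(0, 1))
  xx <- seq(0, 1, length.out = 200)
  graphics::lines(xx, xx^2, lty = 2)
  if (!is.null(fit))
    graphics::lines(xx, xx^stats::median(fit@kBoot), col = 2, lwd = 2)
  invisible(NULL)
}
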