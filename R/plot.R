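#' Heatmap of an 18x18 connectivity matrix
#'
#' Basic image plot with sub-area labels (V1d1..V3v6) and area block
#' separators, matching the conventional presentation of percent
#' connectivity and closeness matrices.
#'
#' @param m 18x18 matrix.
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `m`.
#' @export
plot_connectivity <- function(m, main = "", ...) {
  m <- as.matrix(m)
  nm <- subarea_names()
  graphics::image(1:18, 1:18, t(m[18:1, ]), axes = FALSE,
                  xlab = "", ylab = "", main = main,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  graphics::axis(1, at = 1:18, labels = nm, las = 2, cex.axis = 0.6)
  graphics::axis(2, at = 1:18, labels = rev(nm), las = 2, cex.axis = 0.6)
  graphics::abline(h = c(6.5, 12.5), v = c(6.5, 12.5), col = "grey40")
  invisible(m)
}
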