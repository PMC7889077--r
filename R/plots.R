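#' Plot a significand c.d.f. with its bootstrap band
#'
#' Diagnostic plot: the empirical c.d.f. of significands (step line) with
#' its pointwise bootstrap band, the diagonal (uniform / uncoupled
#' reference) and the step function of perfect integer coupling.
#'
#' @param cdf A [significand_cdf()] object.
#' @return A ggplot object.
#' @export
plot_significand_cdf <- function(cdf) {
  stopifnot(inherits(cdf, "significand_cdf"))
  df <- tibble::tibble(x = cdf$grid, F = cdf$F, lower = cdf$lower,
                       upper = cdf$upper)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.3) +
    ggplot2::geom_step(ggplot2::aes(y = .data$F)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::annotate("segment", x = 0, xend = 1, y = 0.5, yend = 0.5,
                      linetype = "dotted") +
    ggplot2::labs(x = "significand of period ratio",
                  y = "cumulative probability") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1))
}

#' Plot a burst-aligned raster with its column histogram
#'
#' @param raster An [aligned_raster()] object.
#' @return A ggplot object (raster rows; the histogram is available in
#'   `raster$histogram` for separate plotting).
#' @export
plot_aligned_raster <- function(raster) {
  stopifnot(inherits(raster, "aligned_raster"))
  ggplot2::ggplot(raster$rows,
                  ggplot2::aes(x = .data$normalized_time, y = .data$row)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("time from %s burst start (%s periods)",
                  raster$slow_neuron, raster$fast_neuron),
      y = sprintf("%s burst start", raster$slow_neuron))
}
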