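#' Plot grand-mean dERP traces on an electrode grid
#'
#' One small trace panel per electrode, placed at the montage's 2D scalp
#' position (meditators in red, non-meditators in blue when both cells are
#' present), in the style of a full-montage dERP figure.
#'
#' @param grand_means named list of channels x samples matrices (with a
#'   `times` attribute), e.g. the `grand_means` element of a pipeline
#'   bundle.
#' @param montage a [montage].
#' @param experiment which experiment's cells to draw (default "passive").
#' @return Invisibly, `NULL`.
#' @export
plot_derp_grid <- function(grand_means, montage, experiment = "passive") {
  keys <- paste(c("meditator", "non_meditator"), experiment, sep = ".")
  keys <- keys[keys %in% names(grand_means)]
  if (!length(keys)) keys <- names(grand_means)[1]
  gms <- grand_means[keys]
  times <- attr(gms[[1]], "times")
  rng <- range(unlist(lapply(gms, range)))
  graphics::plot.new()
  graphics::plot.window(xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25), asp = 1)
  graphics::symbols(0, 0, circles = 1.15, inches = FALSE, add = TRUE)
  cols <- c("red", "blue")
  pos <- montage$positions
  for (k in seq_len(nrow(pos))) {
    cx <- pos$x[k]; cy <- pos$y[k]
    tx <- cx + 0.34 * (times - min(times)) / diff(range(times)) - 0.17
    for (j in seq_along(gms)) {
      y <- gms[[j]][pos$label[k], ]
      ty <- cy + 0.28 * (y - mean(rng)) / diff(rng)
      graphics::lines(tx, ty, col = cols[j], lwd = 0.8)
    }
    graphics::text(cx, cy + 0.12, pos$label[k], cex = 0.6)
  }
  graphics::title(main = paste("Grand mean dERP traces -", experiment))
  invisible(NULL)
}

#' Scatter plot of individual peak measures
#'
#' Individual subject peak amplitudes per component, split by group, with
#' group means.
#'
#' @param measures a peak-measure data.frame (rows from
#'   [measure_component()], possibly several components combined).
#' @return Invisibly, `NULL`.
#' @export
plot_peak_scatter <- function(measures) {
  comps <- unique(measures$component)
  groups <- c("meditator", "non_meditator")
  cols <- c(meditator = "red", non_meditator = "blue")
  # per subject x component, average over electrodes and experiments
  agg <- stats::aggregate(amplitude_uv ~ subject + group + component,
                          data = measures, FUN = mean)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0.5, length(comps) + 0.5),
                        ylim = range(agg$amplitude_uv))
  graphics::axis(1, at = seq_along(comps), labels = comps)
  graphics::axis(2)
  graphics::abline(h = 0, lty = 3)
  for (i in seq_along(comps)) {
    for (j in seq_along(groups)) {
      v <- agg$amplitude_uv[agg$component == comps[i] & agg$group == groups[j]]
      if (!length(v)) next
      x0 <- i + (j - 1.5) * 0.25
      graphics::points(stats::runif(length(v), x0 - 0.06, x0 + 0.06), v,
                       col = cols[groups[j]], pch = 16, cex = 0.7)
      graphics::points(x0, mean(v), col = cols[groups[j]], pch = 1, cex = 1.6)
    }
  }
  graphics::title(ylab = "peak amplitude (uV)", main = "Individual dERP peaks")
  invisible(NULL)
}
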