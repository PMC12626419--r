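# Minimal base-graphics views of the package's main objects. These helpers
# are conveniences for visual inspection and are not part of the tested
# numerical contract.

#' @export
plot.spectrogram <- function(x, ...) {
  graphics::image(x$times, x$freqs, t(x$values),
                  col = grDevices::hcl.colors(64, "inferno"),
                  xlab = "time (s)", ylab = "frequency (Hz)",
                  main = x$source_id, useRaster = TRUE, ...)
  invisible(x)
}

#' @export
plot.amp_trace <- function(x, ...) {
  graphics::plot(x$times, x$rmse, type = "l", xlab = "time (s)",
                 ylab = "normalized RMSE", main = x$source_id, ...)
  invisible(x)
}

#' @export
plot.rhythm_spectrogram <- function(x, smooth = TRUE, k = 10, ...) {
  v <- if (smooth) smooth_rhythm_spectrogram(x, k = k) else x$values
  graphics::image(seq_len(ncol(v)), x$freqs, t(v),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "file index", ylab = "frequency (Hz)",
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Plot a syntax raster
#'
#' Draws the aligned bout grid from [make_syntax_raster()] with one color
#' per syllable token.
#'
#' @param raster Character matrix from [make_syntax_raster()].
#' @param ... Passed to [graphics::image()].
#' @return The raster, invisibly.
#' @export
plot_syntax_raster <- function(raster, ...) {
  toks <- setdiff(sort(unique(as.character(raster))), "")
  num <- matrix(match(as.character(raster), toks), nrow(raster))
  cols <- grDevices::hcl.colors(max(length(toks), 2L), "Dark 3")
  graphics::image(seq_len(ncol(num)), seq_len(nrow(num)), t(num[rev(seq_len(nrow(num))), , drop = FALSE]),
                  col = cols, xlab = "position", ylab = "bout",
                  useRaster = TRUE, ...)
  graphics::legend("topright", legend = toks, fill = cols[seq_along(toks)],
                   bg = "white", cex = 0.8)
  invisible(raster)
}
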