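#' Normalized entropy of a duration distribution
#'
#' Syllable durations are log10-transformed and binned into 50 evenly spaced
#' bins over `[-2.5, 0]` (i.e. ~3 ms to 1 s); gap durations are binned
#' untransformed into 20 bins of 10 ms up to 200 ms. Bin probabilities `p_i`
#' give `entropy = -sum p_i ln p_i / ln N` with `N` the bin count, so the
#' score lies in `[0, 1]`: 0 when all durations share a bin, 1 for a uniform
#' spread. Durations outside the histogram range are dropped.
#'
#' @param durations Numeric vector of durations in seconds (non-empty).
#' @param kind `"syllable"` or `"gap"`.
#' @return Object of class `duration_distribution`: `bin_edges`, `p`,
#'   `entropy_norm`, `n_used`.
#' @export
duration_entropy <- function(durations, kind = c("syllable", "gap")) {
  kind <- match.arg(kind)
  durations <- as.numeric(durations)
  if (length(durations) == 0L) stop("no durations given", call. = FALSE)
  if (kind == "syllable") {
    edges <- seq(-2.5, 0, length.out = 51L)
    x <- log10(durations[durations > 0])
  } else {
    edges <- seq(0, 0.2, by = 0.01)
    x <- durations
  }
  x <- x[x >= edges[1] & x <= edges[length(edges)]]
  counts <- if (length(x)) {
    tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE),
                  length(edges) - 1L), nbins = length(edges) - 1L)
  } else {
    rep(0L, length(edges) - 1L)
  }
  n_bins <- length(edges) - 1L
  p <- if (sum(counts) > 0) counts / sum(counts) else rep(0, n_bins)
  nz <- p > 0
  ent <- if (any(nz)) -sum(p[nz] * log(p[nz])) / log(n_bins) else NA_real_
  structure(list(bin_edges = edges, p = p, entropy_norm = ent,
                 n_used = length(x), kind = kind),
            class = "duration_distribution")
}

#' Gap durations from a segment table
#'
#' Silent gaps between a syllable offset and the following onset within the
#' same file, capped at `max_gap` seconds (longer gaps are between-bout
#' silences and are excluded).
#'
#' @param segs A [segment_table].
#' @param max_gap Cap in seconds (default 0.2).
#' @return Numeric vector of gap durations.
#' @export
gap_durations <- function(segs, max_gap = 0.2) {
  out <- numeric()
  for (f in unique(segs$file)) {
    sub <- segs[segs$file == f, , drop = FALSE]
    if (nrow(sub) > 1L) {
      g <- sub$onset[-1] - sub$offset[-nrow(sub)]
      out <- c(out, g[g >= 0 & g <= max_gap])
    }
  }
  out
}

#' Rhythm spectrum of one recording
#'
#' The recording's amplitude envelope (normalized RMSE trace, hop 512) is
#' cut into 3-s windows every 0.2 s; the three windows with the highest
#' total amplitude are kept. Per window the first difference of the
#' envelope is mean-centered, Hann-windowed, zero-padded to `n_pad`
#' envelope frames and Fourier-transformed; components below 1 Hz (and
#' above 500 Hz, inert at envelope sampling rates) are masked out. The file
#' spectrum is the mean magnitude spectrum of the three windows, retained
#' over 0-30 Hz. Files shorter than 3.6 s are not eligible.
#'
#' @param rec A [song_rec] (or precomputed `amp_trace`).
#' @param win_s,hop_s Analysis window and hop in seconds.
#' @param n_pad Zero-padded transform length in envelope frames.
#' @param f_lo,f_hi Band-limit in Hz applied by FFT-bin masking.
#' @param keep_hi Upper frequency retained in the output (Hz).
#' @return List of class `rhythm_spectrum`: `spectrum`, `freqs`, `eligible`
#'   (`FALSE` with empty spectrum for too-short files).
#' @export
rhythm_spectrum <- function(rec, win_s = 3, hop_s = 0.2, n_pad = 100000L,
                            f_lo = 1, f_hi = 500, keep_hi = 30) {
  trace <- if (inherits(rec, "amp_trace")) rec else compute_rmse_trace(rec)
  env_rate <- trace$rate / trace$hop
  min_s <- win_s + 3 * hop_s
  if (trace$n_samples / trace$rate < min_s) {
    return(structure(list(spectrum = numeric(), freqs = numeric(),
                          eligible = FALSE, source_id = trace$source_id),
                     class = "rhythm_spectrum"))
  }
  wlen <- round(win_s * env_rate)
  hlen <- max(1L, round(hop_s * env_rate))
  n <- length(trace$rmse)
  starts <- seq(1L, n - wlen + 1L, by = hlen)
  amp <- vapply(starts, function(s) sum(trace$rmse[s:(s + wlen - 1L)]),
                numeric(1))
  top <- starts[order(-amp)[seq_len(min(3L, length(starts)))]]
  freqs_all <- (seq_len(n_pad) - 1L) * env_rate / n_pad
  keep_band <- freqs_all >= f_lo & freqs_all <= min(f_hi, env_rate / 2)
  out_idx <- which(freqs_all <= keep_hi & freqs_all <= env_rate / 2)
  specs <- vapply(top, function(s) {
    d <- diff(trace$rmse[s:(s + wlen - 1L)])
    d <- (d - mean(d)) * .hann(length(d))
    padded <- c(d, numeric(n_pad - length(d)))
    sp <- Mod(stats::fft(padded))
    sp[!keep_band] <- 0
    sp[out_idx]
  }, numeric(length(out_idx)))
  structure(list(spectrum = rowMeans(specs), freqs = freqs_all[out_idx],
                 eligible = TRUE, source_id = trace$source_id),
            class = "rhythm_spectrum")
}

#' Rhythm spectrogram across recordings
#'
#' Stacks the per-file rhythm spectra of a recording set into a matrix
#' (frequency x file). Files shorter than the minimum duration are skipped;
#' at least one eligible file is required. The raw spectra are used for all
#' features; [smooth_rhythm_spectrogram()] provides the rolling-average view
#' used for visualization.
#'
#' @param recs List of [song_rec]s (or `amp_trace`s).
#' @param ... Passed to [rhythm_spectrum()].
#' @return Object of class `rhythm_spectrogram`: `values` (freq x file),
#'   `freqs`, `files`, `skipped`.
#' @export
rhythm_spectrogram <- function(recs, ...) {
  specs <- lapply(recs, rhythm_spectrum, ...)
  ok <- vapply(specs, function(s) s$eligible, logical(1))
  if (!any(ok)) {
    stop("no recording is long enough for rhythm analysis", call. = FALSE)
  }
  kept <- specs[ok]
  values <- do.call(cbind, lapply(kept, `[[`, "spectrum"))
  colnames(values) <- vapply(kept, `[[`, character(1), "source_id")
  structure(list(values = values, freqs = kept[[1]]$freqs,
                 files = colnames(values),
                 skipped = vapply(specs[!ok], `[[`, character(1), "source_id")),
            class = "rhythm_spectrogram")
}

#' Rolling-average rhythm spectrogram for visualization
#'
#' @param rs A `rhythm_spectrogram`.
#' @param k Rolling-window width in files (default 10).
#' @return Matrix with the same shape as `rs$values`.
#' @export
smooth_rhythm_spectrogram <- function(rs, k = 10) {
  v <- rs$values
  n <- ncol(v)
  out <- v
  for (j in seq_len(n)) {
    lo <- max(1L, j - k + 1L)
    out[, j] <- rowMeans(v[, lo:j, drop = FALSE])
  }
  out
}

#' Wiener entropy of the mean rhythm spectrum
#'
#' `mean(ln power) - ln(mean power)` of the squared mean rhythm spectrum
#' over the retained band, using only bins with non-zero power (bins zeroed
#' by the 1 Hz high-pass are excluded). The score is 0 for a flat power
#' spectrum and increasingly negative as power concentrates in few bins
#' (strong, harmonic rhythm).
#'
#' @param rs A `rhythm_spectrogram`.
#' @return Single numeric `<= 0`.
#' @export
rhythm_entropy <- function(rs) {
  stopifnot(inherits(rs, "rhythm_spectrogram"), ncol(rs$values) >= 1L)
  m <- rowMeans(rs$values)
  p <- m^2
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  mean(log(p)) - log(mean(p))
}

#' Peak-frequency variability of the rhythm spectrogram
#'
#' Per-file peak frequencies are first located freely; each file's peak is
#' then re-located within a 3 Hz band centered on the median peak (median
#' +/- 1.5 Hz), so jumps between harmonic bands do not inflate the score.
#' Returns the population CV of the constrained peaks.
#'
#' @param rs A `rhythm_spectrogram` with at least two files.
#' @param band Full width of the constraint band in Hz (default 3).
#' @return Single non-negative numeric.
#' @export
peak_freq_cv <- function(rs, band = 3) {
  stopifnot(inherits(rs, "rhythm_spectrogram"))
  if (ncol(rs$values) < 2L) {
    stop("peak frequency variability needs at least 2 eligible files",
         call. = FALSE)
  }
  free_peaks <- rs$freqs[apply(rs$values, 2, which.max)]
  med <- stats::median(free_peaks)
  in_band <- rs$freqs >= med - band / 2 & rs$freqs <= med + band / 2
  if (!any(in_band)) in_band <- rep(TRUE, length(rs$freqs))
  sub <- rs$values[in_band, , drop = FALSE]
  peaks <- rs$freqs[in_band][apply(sub, 2, which.max)]
  .pop_cv(peaks)
}

#' Timing feature bundle
#'
#' @param segs A [segment_table] (labels not required).
#' @param recs List of [song_rec]s for rhythm analysis.
#' @return List of class `timing_features`: `syll_duration_entropy`,
#'   `gap_duration_entropy`, `rhythm_spectrum_entropy`, `peak_freq_cv`.
#' @export
timing_features <- function(segs, recs) {
  syll <- duration_entropy(segs$offset - segs$onset, "syllable")
  gaps <- gap_durations(segs)
  gap_ent <- if (length(gaps)) duration_entropy(gaps, "gap")$entropy_norm else NA_real_
  rs <- tryCatch(rhythm_spectrogram(recs), error = function(e) NULL)
  re <- if (is.null(rs)) NA_real_ else rhythm_entropy(rs)
  pf <- if (is.null(rs) || ncol(rs$values) < 2L) NA_real_ else peak_freq_cv(rs)
  structure(list(syll_duration_entropy = syll$entropy_norm,
                 gap_duration_entropy = gap_ent,
                 rhythm_spectrum_entropy = re,
                 peak_freq_cv = pf),
            class = "timing_features")
}
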