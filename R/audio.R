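#' Mono audio recording
#'
#' Lightweight container for a single-channel recording. All analysis
#' functions in the package take `song_rec` objects rather than file paths.
#'
#' @param samples Numeric vector of amplitudes (dimensionless).
#' @param rate Sampling rate in samples/second.
#' @param source_id Opaque identifier tying segments back to this recording.
#' @return An object of class `song_rec`.
#' @export
song_rec <- function(samples, rate, source_id = "rec") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("samples must be non-empty", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a single positive number", call. = FALSE)
  }
  structure(list(samples = samples, rate = as.numeric(rate),
                 source_id = as.character(source_id)),
            class = "song_rec")
}

#' @export
print.song_rec <- function(x, ...) {
  cat(sprintf("<song_rec '%s': %d samples @ %g Hz (%.3f s)>\n",
              x$source_id, length(x$samples), x$rate,
              length(x$samples) / x$rate))
  invisible(x)
}

#' Zero-phase bandpass filter
#'
#' Butterworth bandpass applied forward and backward (`signal::filtfilt`),
#' so the output has no group delay and segment timestamps computed on the
#' filtered signal stay aligned with the raw audio.
#'
#' @param rec A [song_rec].
#' @param lo,hi Passband edges in Hz; `0 < lo < hi < rate/2`.
#' @param order Butterworth order of the one-way filter (applied twice).
#' @return A filtered [song_rec] of identical length and rate.
#' @export
bandpass <- function(rec, lo, hi, order = 4) {
  stopifnot(inherits(rec, "song_rec"))
  nyq <- rec$rate / 2
  if (!(lo > 0 && lo < hi)) stop("need 0 < lo < hi", call. = FALSE)
  if (hi >= nyq) {
    stop("hi (", hi, " Hz) must be below the Nyquist frequency (", nyq, " Hz)",
         call. = FALSE)
  }
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  out <- signal::filtfilt(bf, rec$samples)
  song_rec(out, rec$rate, rec$source_id)
}

#' Per-frame RMS energy trace
#'
#' Root-mean-square energy of centered frames (signal reflect-padded by half
#' a frame on each side), one frame every `hop` samples; frame `k` (0-based)
#' is timestamped `k * hop / rate` seconds. By default the trace is min-max
#' normalized to `[0, 1]` per file so that a single global segmentation
#' threshold is meaningful across recordings.
#'
#' A second RMSE trace at finer resolution (frame 256, hop 64 by default)
#' is attached as `fine_rmse`/`fine_hop`; segmentation uses it only to
#' refine detected onset timestamps below the resolution of the main
#' frames, never for detection itself.
#'
#' @param rec A [song_rec] of length at least `frame_len`.
#' @param hop,frame_len Hop and frame length in samples.
#' @param normalize Min-max normalize the trace to `[0, 1]`.
#' @param fine_hop,fine_frame Parameters of the auxiliary fine trace; set
#'   `fine_hop = NULL` to skip it.
#' @return An object of class `amp_trace` with elements `rmse`, `times`,
#'   `hop`, `frame_len`, `rate`, `source_id` (plus the fine trace).
#' @export
compute_rmse_trace <- function(rec, hop = 512, frame_len = 2048,
                               normalize = TRUE, fine_hop = 64,
                               fine_frame = 256) {
  stopifnot(inherits(rec, "song_rec"))
  n <- length(rec$samples)
  if (n < frame_len) {
    stop("recording too short (", n, " samples) for frame length ", frame_len,
         call. = FALSE)
  }
  one_trace <- function(hp, fl) {
    padded <- .reflect_pad(rec$samples, fl %/% 2L)
    n_frames <- 1L + n %/% hp
    starts <- (seq_len(n_frames) - 1L) * hp
    idx <- outer(seq_len(fl), starts, `+`)
    sqrt(colMeans(matrix(padded[idx], nrow = fl)^2))
  }
  norm01 <- function(x) {
    rng <- range(x)
    if (diff(rng) > 0) (x - rng[1]) / diff(rng) else rep(0, length(x))
  }
  rmse <- one_trace(hop, frame_len)
  if (normalize) rmse <- norm01(rmse)
  fine <- NULL
  if (!is.null(fine_hop)) {
    fine <- one_trace(fine_hop, fine_frame)
    if (normalize) fine <- norm01(fine)
  }
  structure(list(rmse = rmse,
                 times = (seq_len(length(rmse)) - 1L) * hop / rec$rate,
                 hop = hop, frame_len = frame_len, rate = rec$rate,
                 n_samples = n, source_id = rec$source_id,
                 fine_rmse = fine, fine_hop = fine_hop,
                 fine_frame = fine_frame),
            class = "amp_trace")
}

.reflect_pad <- function(x, pad) {
  n <- length(x)
  if (pad <= 0L) return(x)
  if (pad >= n) {       # repeat reflection for very short signals
    left <- rev(rep_len(c(x[-1], rev(x)[-1]), pad))
    right <- rep_len(c(rev(x)[-1], x[-1]), pad)
    return(c(left, x, right))
  }
  c(rev(x[2:(pad + 1L)]), x, rev(x)[2:(pad + 1L)])
}

#' dB-scaled magnitude spectrogram
#'
#' Short-time Fourier transform with a Hann window and centered,
#' reflect-padded frames. Magnitudes are converted to decibels referenced to
#' the maximum magnitude of the file (`20 log10(max(m, eps * ref) / ref)`),
#' with a small floor `eps` so an all-zero signal yields a finite uniform
#' floor rather than `-Inf`.
#'
#' @param rec A [song_rec].
#' @param window_len FFT/window length in samples.
#' @param hop Hop length in samples (must be positive).
#' @param db Convert magnitudes to dB (re file max). If `FALSE`, raw
#'   magnitudes are returned.
#' @param eps Relative magnitude floor used in the dB conversion.
#' @return An object of class `spectrogram`: `values` (freq x time), `freqs`
#'   (Hz), `times` (s), `window_len`, `hop`.
#' @export
make_spectrogram <- function(rec, window_len = 512, hop = 128, db = TRUE,
                             eps = 1e-10) {
  stopifnot(inherits(rec, "song_rec"))
  if (hop <= 0) stop("hop must be positive", call. = FALSE)
  n <- length(rec$samples)
  if (window_len > n) {
    stop("window_len (", window_len, ") exceeds recording length (", n, ")",
         call. = FALSE)
  }
  mag <- .stft_mag(rec$samples, window_len, hop)
  freqs <- (seq_len(nrow(mag)) - 1L) * rec$rate / window_len
  times <- (seq_len(ncol(mag)) - 1L) * hop / rec$rate
  if (db) {
    ref <- max(mag)
    if (ref <= 0) {
      vals <- matrix(0, nrow(mag), ncol(mag))
    } else {
      vals <- 20 * log10(pmax(mag, eps * ref) / ref)
    }
  } else {
    vals <- mag
  }
  structure(list(values = vals, freqs = freqs, times = times,
                 window_len = window_len, hop = hop, rate = rec$rate,
                 source_id = rec$source_id),
            class = "spectrogram")
}

# magnitude STFT on centered reflect-padded frames; rows = window_len/2 + 1 bins
.stft_mag <- function(x, window_len, hop) {
  n <- length(x)
  padded <- .reflect_pad(x, window_len %/% 2L)
  n_frames <- 1L + n %/% hop
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(window_len), starts, `+`)
  fr <- matrix(padded[idx], nrow = window_len)
  w <- .hann(window_len)
  sp <- stats::mvfft(fr * w)
  Mod(sp[seq_len(window_len %/% 2L + 1L), , drop = FALSE])
}

# periodic Hann window (standard STFT convention)
.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)
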