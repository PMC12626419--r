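#' Frame-level acoustic features
#'
#' Computes, per spectrogram frame, the seven acoustic features used for
#' phenotyping. Operational definitions (fixed and frozen by regression
#' tests; parity with external tools is not claimed):
#' * `amplitude`: `10 log10(frame power)` in dB (recording-sensitive);
#' * `wiener_entropy`: `mean(ln power) - ln(mean power)` over frequency,
#'   0 for flat (noise-like) spectra, strongly negative for tonal frames;
#' * `mean_frequency`: power-weighted spectral centroid in Hz;
#' * `pitch`: frequency of the largest cepstral peak within `pitch_range`;
#' * `goodness_of_pitch`: height of that cepstral peak;
#' * `amplitude_modulation`: summed time-derivative of spectral power
#'   (recording-sensitive);
#' * `frequency_modulation`: `atan` of the ratio of root-summed-squared
#'   time to frequency derivatives of the power spectrogram.
#'
#' Silent frames receive finite floor values, never `NaN`.
#'
#' @param rec A [song_rec].
#' @param window_len,hop STFT parameters in samples.
#' @param pitch_range Allowed pitch range in Hz for the cepstral search.
#' @return Data frame of class `acoustic_frames`, one row per frame, with a
#'   `time` column (s) and one column per feature.
#' @export
frame_features <- function(rec, window_len = 512, hop = 128,
                           pitch_range = c(350, 6000)) {
  stopifnot(inherits(rec, "song_rec"))
  mag <- .stft_mag(rec$samples, window_len, hop)
  P <- mag^2
  n_bins <- nrow(P); n_frames <- ncol(P)
  freqs <- (seq_len(n_bins) - 1L) * rec$rate / window_len
  eps <- 1e-12
  tot <- colSums(P)
  amplitude <- 10 * log10(tot + eps)
  # spectral floor relative to the frame maximum, so ratio-based features
  # (Wiener entropy, cepstrum) are invariant to overall gain
  floorP <- sweep(P, 2, pmax(apply(P, 2, max) * eps, .Machine$double.xmin),
                  pmax)
  wiener <- colMeans(log(floorP)) - log(colMeans(floorP))
  mean_frequency <- colSums(P * freqs) / (tot + eps)
  # cepstrum from the full symmetric log-power spectrum; the power spectrum
  # is lightly smoothed (3-bin moving average) first to tame the chi-squared
  # speckle of single-taper spectra, which otherwise inflates the cepstral
  # peak of noise frames
  q_lo <- max(2L, floor(rec$rate / pitch_range[2]))
  q_hi <- min(window_len %/% 2L, ceiling(rec$rate / pitch_range[1]))
  Ps <- (rbind(P[1, ], P[-n_bins, ]) + P + rbind(P[-1, ], P[n_bins, ])) / 3
  flS <- pmax(apply(Ps, 2, max) * eps, .Machine$double.xmin)
  lp <- log(sweep(Ps, 2, flS, pmax))
  full <- rbind(lp, lp[rev(seq(2L, n_bins - 1L)), , drop = FALSE])
  cep <- Re(stats::mvfft(full, inverse = TRUE)) / nrow(full)
  qrange <- seq(q_lo + 1L, q_hi + 1L)     # +1: row 1 is quefrency 0
  peak_q <- apply(cep[qrange, , drop = FALSE], 2, which.max) + q_lo - 1L
  goodness <- cep[cbind(peak_q + 1L, seq_len(n_frames))]
  pitch <- rec$rate / peak_q
  dT <- cbind(0, P[, -1L, drop = FALSE] - P[, -n_frames, drop = FALSE])
  dF <- rbind(0, P[-1L, , drop = FALSE] - P[-n_bins, , drop = FALSE])
  am <- colSums(dT)
  fm <- atan(sqrt(colSums(dT^2)) / (sqrt(colSums(dF^2)) + eps))
  out <- data.frame(time = (seq_len(n_frames) - 1L) * hop / rec$rate,
                    goodness_of_pitch = goodness,
                    mean_frequency = mean_frequency,
                    wiener_entropy = wiener,
                    amplitude = amplitude,
                    amplitude_modulation = am,
                    frequency_modulation = fm,
                    pitch = pitch)
  class(out) <- c("acoustic_frames", "data.frame")
  out
}

# the eight per-syllable base features (seven acoustic + duration)
.base_features <- c("goodness_of_pitch", "mean_frequency", "wiener_entropy",
                    "amplitude", "amplitude_modulation",
                    "frequency_modulation", "pitch", "duration")

#' Per-type acoustic summary
#'
#' For every syllable rendition, each frame feature is averaged over the
#' frames falling inside the segment, and the syllable duration is appended
#' as the eighth base feature. Per syllable type the mean of those
#' rendition means and the population CV across renditions are returned;
#' the CV is only defined for types with at least two renditions.
#'
#' @param recs Named list of [song_rec]s (names = file ids), or a single
#'   `song_rec`.
#' @param segs A labelled [segment_table].
#' @param ... Passed to [frame_features()].
#' @return Data frame of class `acoustic_summary`: one row per type with
#'   `label`, `n_renditions`, and `<feature>_mean` / `<feature>_cv` columns
#'   for the eight base features. The recording-sensitive columns
#'   (amplitude and amplitude-modulation) are listed in
#'   `attr(x, "recording_sensitive")`.
#' @export
summarize_by_type <- function(recs, segs, ...) {
  if (inherits(recs, "song_rec")) {
    recs <- stats::setNames(list(recs), recs$source_id)
  }
  miss <- setdiff(unique(segs$file), names(recs))
  if (length(miss)) {
    stop("no recording supplied for file(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  per_rendition <- list()
  for (f in unique(segs$file)) {
    ff <- frame_features(recs[[f]], ...)
    sub <- segs[segs$file == f, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      inside <- ff$time >= sub$onset[i] & ff$time < sub$offset[i]
      if (!any(inside)) {
        inside <- which.min(abs(ff$time - (sub$onset[i] + sub$offset[i]) / 2))
      }
      m <- colMeans(ff[inside, setdiff(names(ff), "time"), drop = FALSE])
      per_rendition[[length(per_rendition) + 1L]] <-
        c(list(label = sub$label[i], duration = sub$offset[i] - sub$onset[i]),
          as.list(m))
    }
  }
  pr <- do.call(rbind, lapply(per_rendition, as.data.frame))
  out <- do.call(rbind, lapply(sort(unique(pr$label)), function(lab) {
    sub <- pr[pr$label == lab, , drop = FALSE]
    row <- data.frame(label = lab, n_renditions = nrow(sub))
    for (feat in .base_features) {
      v <- sub[[feat]]
      row[[paste0(feat, "_mean")]] <- mean(v)
      row[[paste0(feat, "_cv")]] <-
        if (nrow(sub) >= 2L) .pop_cv_signed(v) else NA_real_
    }
    row
  }))
  rownames(out) <- NULL
  attr(out, "recording_sensitive") <-
    grep("^amplitude", names(out), value = TRUE)
  class(out) <- c("acoustic_summary", "data.frame")
  out
}

# CV defined via |mean| so sign-varying features (e.g. Wiener entropy)
# still yield a non-negative dispersion ratio
.pop_cv_signed <- function(x) {
  m <- mean(x)
  if (abs(m) < 1e-12) return(NA_real_)
  sqrt(mean((x - m)^2)) / abs(m)
}

# lower median: for an even count, the smaller of the two central values
.lower_median <- function(x) {
  x <- sort(x[!is.na(x)])
  if (length(x) == 0L) return(NA_real_)
  x[ceiling(length(x) / 2)]
}

#' Assemble the 55-feature phenotype vector
#'
#' For each of the eight base features and each of mean / CV, the minimum,
#' (lower) median and maximum across syllable types are taken — 48 acoustic
#' summary values — followed by three syntax features (normalized entropy
#' rate, mean and CV of the selected type's repetition-bout length) and four
#' timing features (syllable- and gap-duration entropies, rhythm-spectrum
#' Wiener entropy, peak-frequency CV): 55 named values in a fixed order.
#' Missing components yield `NA` entries, never silent imputation.
#'
#' @param acoustic An `acoustic_summary` (or `NULL`).
#' @param syntax A `syntax_features` (or `NULL`).
#' @param timing A `timing_features` (or `NULL`).
#' @param exclude_noise Drop the reserved `"noise"` cluster type from the
#'   acoustic summary before summarizing across types.
#' @return Named numeric vector of length 55 (or 48 if only the acoustic
#'   block is requested via `syntax = timing = NULL` and
#'   `acoustic_only = TRUE`).
#' @param acoustic_only Return only the 48 acoustic summaries.
#' @export
assemble_feature_vector <- function(acoustic, syntax = NULL, timing = NULL,
                                    exclude_noise = TRUE,
                                    acoustic_only = FALSE) {
  vals <- numeric(0)
  if (!is.null(acoustic) && exclude_noise) {
    acoustic <- acoustic[acoustic$label != "noise", , drop = FALSE]
  }
  for (feat in .base_features) {
    for (stat in c("mean", "cv")) {
      col <- if (is.null(acoustic)) rep(NA_real_, 0) else
        acoustic[[paste0(feat, "_", stat)]]
      col <- col[!is.na(col)]
      trio <- if (length(col)) {
        c(min(col), .lower_median(col), max(col))
      } else {
        rep(NA_real_, 3)
      }
      names(trio) <- paste0(feat, "_", stat, "_", c("min", "median", "max"))
      vals <- c(vals, trio)
    }
  }
  if (acoustic_only) return(vals)
  syn <- c(entropy_rate_norm = if (is.null(syntax)) NA_real_ else syntax$entropy_rate_norm,
           mean_rep_bout_len = if (is.null(syntax)) NA_real_ else syntax$mean_rep_bout_len,
           cv_rep_bout_len = if (is.null(syntax)) NA_real_ else syntax$cv_rep_bout_len)
  tim <- c(syll_duration_entropy = if (is.null(timing)) NA_real_ else timing$syll_duration_entropy,
           gap_duration_entropy = if (is.null(timing)) NA_real_ else timing$gap_duration_entropy,
           rhythm_spectrum_entropy = if (is.null(timing)) NA_real_ else timing$rhythm_spectrum_entropy,
           peak_freq_cv = if (is.null(timing)) NA_real_ else timing$peak_freq_cv)
  c(vals, syn, tim)
}
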