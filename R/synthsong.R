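#' Syllable archetype for synthetic song
#'
#' A syllable type is synthesized as an additive harmonic stack with an
#' optional linear frequency sweep and an adjustable broadband-noise mix —
#' the simplest signal family that exercises pitch, goodness of pitch,
#' Wiener entropy and frequency-modulation features simultaneously.
#'
#' @param fundamental Fundamental frequency in Hz.
#' @param n_harmonics Number of harmonics (including the fundamental).
#' @param rolloff Per-harmonic amplitude factor in (0, 1].
#' @param dur_mean Mean syllable duration in seconds.
#' @param dur_jitter Standard deviation of per-rendition duration (s).
#' @param sweep Linear frequency-sweep slope in Hz/s applied to the
#'   fundamental (harmonics scale along).
#' @param noisiness Fraction in `[0, 1]` of broadband noise mixed in.
#' @return A list of class `syll_archetype`.
#' @export
syll_archetype <- function(fundamental, n_harmonics = 5, rolloff = 0.7,
                           dur_mean = 0.08, dur_jitter = 0.004, sweep = 0,
                           noisiness = 0.05) {
  stopifnot(dur_mean > 0, fundamental > 0, n_harmonics >= 1,
            noisiness >= 0, noisiness <= 1)
  structure(list(fundamental = fundamental, n_harmonics = n_harmonics,
                 rolloff = rolloff, dur_mean = dur_mean,
                 dur_jitter = dur_jitter, sweep = sweep,
                 noisiness = noisiness),
            class = "syll_archetype")
}

#' Song grammar for synthetic bouts
#'
#' Bouts consist of a geometric number of introductory notes followed by
#' repeated passes through a motif. With probability `epsilon` each
#' within-bout transition is replaced by a jump to a uniformly random
#' syllable type, so `epsilon = 0` yields a fully stereotyped (adult-like)
#' grammar and large `epsilon` a variable (juvenile-like) one.
#'
#' @param motif Character vector of archetype tokens forming the motif.
#' @param intro Token used as the introductory note (`NULL` for none).
#' @param intro_p Success probability of the geometric intro-repeat count
#'   (number of intro notes = 1 + rgeom(intro_p)).
#' @param epsilon Probability of a random off-motif transition.
#' @param gap_mean,gap_jitter Intra-bout silent-gap mean and s.d. (s);
#'   gaps are clamped below 0.2 s so bouts stay intact.
#' @param repeat_p If non-`NULL`, the first motif syllable is produced
#'   `1 + rgeom(repeat_p)` times per pass (exercises repetition analysis).
#' @param passes Motif passes per bout: `NULL` for the default
#'   `2 + rgeom(0.6)` (bouts loop the motif a few times), or a fixed
#'   positive integer.
#' @return A list of class `song_grammar`.
#' @export
song_grammar <- function(motif, intro = "i", intro_p = 0.5, epsilon = 0,
                         gap_mean = 0.06, gap_jitter = 0.008,
                         repeat_p = NULL, passes = NULL) {
  stopifnot(length(motif) >= 1, epsilon >= 0, epsilon <= 1, gap_mean > 0)
  if (gap_mean + 4 * gap_jitter >= 0.2) {
    stop("gap_mean/gap_jitter would produce intra-bout gaps >= 200 ms",
         call. = FALSE)
  }
  structure(list(motif = as.character(motif), intro = intro,
                 intro_p = intro_p, epsilon = epsilon, gap_mean = gap_mean,
                 gap_jitter = gap_jitter, repeat_p = repeat_p,
                 passes = passes),
            class = "song_grammar")
}

#' Full specification for a synthetic song dataset
#'
#' @param grammar A [song_grammar].
#' @param archetypes Named list of [syll_archetype]s covering every token in
#'   the grammar.
#' @param n_files Number of WAV files to render.
#' @param bouts_per_file Bouts per file.
#' @param rate Sample rate in Hz.
#' @param noise_floor RMS amplitude of the background noise floor.
#' @param cage_noise_rate Expected number of broadband cage-noise bursts per
#'   file (labelled `"noise"` in the truth table).
#' @param seed Integer seed; fully determines the rendered bytes.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(grammar, archetypes, n_files = 5, bouts_per_file = 3,
                       rate = 32000, noise_floor = 1e-3,
                       cage_noise_rate = 0, seed = 1) {
  toks <- unique(c(grammar$motif, grammar$intro))
  toks <- toks[!is.null(toks)]
  miss <- setdiff(toks, names(archetypes))
  if (length(miss)) {
    stop("archetypes missing for token(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  structure(list(grammar = grammar, archetypes = archetypes,
                 n_files = n_files, bouts_per_file = bouts_per_file,
                 rate = rate, noise_floor = noise_floor,
                 cage_noise_rate = cage_noise_rate, seed = as.integer(seed)),
            class = "synth_spec")
}

# one syllable rendition waveform
.render_syllable <- function(arch, dur, rate) {
  n <- max(16L, round(dur * rate))
  t <- (seq_len(n) - 1L) / rate
  f0 <- arch$fundamental + arch$sweep * t
  # phase by integrating instantaneous frequency
  phase0 <- 2 * pi * cumsum(f0) / rate
  x <- numeric(n)
  for (h in seq_len(arch$n_harmonics)) {
    fh_max <- (arch$fundamental + abs(arch$sweep) * dur) * h
    if (fh_max >= rate / 2) break
    x <- x + arch$rolloff^(h - 1) * sin(h * phase0)
  }
  if (arch$noisiness > 0) {
    ns <- stats::rnorm(n)
    x <- (1 - arch$noisiness) * x + arch$noisiness * ns * stats::sd(x)
  }
  # raised-cosine edges (5 ms) to avoid clicks
  edge <- min(round(0.005 * rate), n %/% 4L)
  if (edge > 1L) {
    ramp <- 0.5 - 0.5 * cos(pi * (seq_len(edge) - 1L) / (edge - 1L))
    x[seq_len(edge)] <- x[seq_len(edge)] * ramp
    x[(n - edge + 1L):n] <- x[(n - edge + 1L):n] * rev(ramp)
  }
  x / max(abs(x), 1e-12) * 0.5
}

# label sequence for one bout
.bout_labels <- function(g) {
  toks <- character()
  if (!is.null(g$intro)) {
    toks <- rep(g$intro, 1L + stats::rgeom(1, g$intro_p))
  }
  # a bout holds several motif passes (real bouts loop the motif)
  passes <- if (is.null(g$passes)) 2L + stats::rgeom(1, 0.6) else g$passes
  for (p in seq_len(passes)) {
    for (j in seq_along(g$motif)) {
      tok <- g$motif[j]
      reps <- 1L
      if (!is.null(g$repeat_p) && j == 1L) {
        reps <- 1L + stats::rgeom(1, g$repeat_p)
      }
      for (r in seq_len(reps)) {
        if (g$epsilon > 0 && stats::runif(1) < g$epsilon) {
          tok <- sample(g$motif, 1)
        }
        toks <- c(toks, tok)
      }
    }
  }
  toks
}

#' Render a synthetic song dataset
#'
#' Produces one mono recording per file plus a ground-truth [segment_table]
#' with syllable labels (and `"noise"` rows for cage-noise bursts). Output is
#' a deterministic function of `spec$seed`: per-file RNG substreams are
#' derived from it, and 16-bit quantization makes written WAVs byte-identical
#' across runs.
#'
#' @param spec A [synth_spec].
#' @param dir Output directory for WAV files, or `NULL` to keep recordings
#'   in memory only.
#' @return List with `recs` (named list of [song_rec]), `truth` (a labelled
#'   [segment_table]), and `paths` (WAV paths, or `NULL`).
#' @export
render_song <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  g <- spec$grammar
  rate <- spec$rate
  recs <- list()
  rows <- list()
  paths <- if (is.null(dir)) NULL else character(spec$n_files)
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (fidx in seq_len(spec$n_files)) {
    set.seed(spec$seed * 10007L + fidx)
    fid <- sprintf("synth_%03d", fidx)
    chunks <- list(numeric(round(0.35 * rate)))
    t_cursor <- 0.35
    for (b in seq_len(spec$bouts_per_file)) {
      labels <- .bout_labels(g)
      for (j in seq_along(labels)) {
        arch <- spec$archetypes[[labels[j]]]
        dur <- max(0.02, stats::rnorm(1, arch$dur_mean, arch$dur_jitter))
        wav <- .render_syllable(arch, dur, rate)
        chunks[[length(chunks) + 1L]] <- wav
        rows[[length(rows) + 1L]] <- data.frame(
          file = fid, onset = t_cursor,
          offset = t_cursor + length(wav) / rate, label = labels[j])
        t_cursor <- t_cursor + length(wav) / rate
        if (j < length(labels)) {
          gap <- min(0.19, max(0.02, stats::rnorm(1, g$gap_mean, g$gap_jitter)))
          chunks[[length(chunks) + 1L]] <- numeric(round(gap * rate))
          t_cursor <- t_cursor + round(gap * rate) / rate
        }
      }
      sil <- stats::runif(1, 0.45, 0.8)
      n_noise <- if (spec$cage_noise_rate > 0) stats::rpois(1, spec$cage_noise_rate / spec$bouts_per_file) else 0L
      if (n_noise > 0L) {
        # drop a broadband burst inside the inter-bout silence
        pre <- stats::runif(1, 0.25, 0.35)
        ndur <- stats::runif(1, 0.05, 0.12)
        chunks[[length(chunks) + 1L]] <- numeric(round(pre * rate))
        burst <- stats::rnorm(round(ndur * rate)) * 0.3
        chunks[[length(chunks) + 1L]] <- burst
        rows[[length(rows) + 1L]] <- data.frame(
          file = fid, onset = t_cursor + round(pre * rate) / rate,
          offset = t_cursor + (round(pre * rate) + length(burst)) / rate,
          label = "noise")
        rest <- max(0.25, sil - pre - ndur)
        chunks[[length(chunks) + 1L]] <- numeric(round(rest * rate))
        t_cursor <- t_cursor +
          (round(pre * rate) + length(burst) + round(rest * rate)) / rate
      } else {
        chunks[[length(chunks) + 1L]] <- numeric(round(sil * rate))
        t_cursor <- t_cursor + round(sil * rate) / rate
      }
    }
    x <- unlist(chunks, use.names = FALSE)
    if (spec$noise_floor > 0) x <- x + stats::rnorm(length(x), 0, spec$noise_floor)
    x <- pmax(pmin(x, 1), -1)
    x <- round(x * 32767) / 32767          # 16-bit quantization, in memory too
    rec <- song_rec(x, rate, fid)
    recs[[fid]] <- rec
    if (!is.null(dir)) {
      paths[fidx] <- file.path(dir, paste0(fid, ".wav"))
      write_wav(rec, paths[fidx])
    }
  }
  truth <- do.call(rbind, rows)
  truth <- segment_table(truth$file, truth$onset, truth$offset, truth$label)
  list(recs = recs, truth = truth, paths = paths)
}

#' Preset synthetic-song regimes
#'
#' Parameter bundles mirroring the study groups the generator emulates:
#' `"adult"` (stereotyped song: near-deterministic motif, small duration and
#' gap jitter), `"juvenile"` (duration jitter x5 and half-random
#' transitions), `"isolate_like"` (reduced repertoire, noisy variable
#' syllables, loose syntax) and `"repeater"` (an adult grammar whose first
#' motif syllable is repeated a geometric number of times, mean > 2).
#'
#' @param name One of `"adult"`, `"juvenile"`, `"isolate_like"`,
#'   `"repeater"`.
#' @param n_files,bouts_per_file,seed Passed through to [synth_spec()].
#' @return A [synth_spec].
#' @export
synth_preset <- function(name = c("adult", "juvenile", "isolate_like", "repeater"),
                         n_files = 6, bouts_per_file = 3, seed = 1) {
  name <- match.arg(name)
  arch <- list(
    i = syll_archetype(650, 3, 0.8, dur_mean = 0.045, dur_jitter = 0.003,
                       sweep = -1500, noisiness = 0.05),
    a = syll_archetype(900, 6, 0.75, dur_mean = 0.085, dur_jitter = 0.004,
                       sweep = 0, noisiness = 0.03),
    b = syll_archetype(1800, 4, 0.6, dur_mean = 0.120, dur_jitter = 0.005,
                       sweep = 4000, noisiness = 0.05),
    c = syll_archetype(3000, 3, 0.5, dur_mean = 0.060, dur_jitter = 0.003,
                       sweep = -6000, noisiness = 0.25)
  )
  jitter_up <- function(a, k) {
    a$dur_jitter <- a$dur_jitter * k
    a
  }
  spec <- switch(
    name,
    adult = synth_spec(
      song_grammar(c("a", "b", "c"), intro = "i", intro_p = 0.5,
                   epsilon = 0.01, gap_mean = 0.06, gap_jitter = 0.006),
      arch, n_files, bouts_per_file, seed = seed),
    juvenile = synth_spec(
      song_grammar(c("a", "b", "c"), intro = "i", intro_p = 0.5,
                   epsilon = 0.5, gap_mean = 0.07, gap_jitter = 0.02),
      lapply(arch, jitter_up, k = 5), n_files, bouts_per_file, seed = seed),
    isolate_like = synth_spec(
      song_grammar(c("a", "b"), intro = "i", intro_p = 0.4,
                   epsilon = 0.35, gap_mean = 0.08, gap_jitter = 0.02),
      lapply(arch[c("i", "a", "b")], function(a) {
        a$noisiness <- min(1, a$noisiness + 0.3)
        jitter_up(a, 4)
      }), n_files, bouts_per_file, seed = seed),
    repeater = synth_spec(
      song_grammar(c("a", "b", "c"), intro = "i", intro_p = 0.5,
                   epsilon = 0.01, gap_mean = 0.06, gap_jitter = 0.006,
                   repeat_p = 0.4),
      arch, n_files, bouts_per_file, seed = seed)
  )
  spec
}
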