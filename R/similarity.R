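#' Fixed-size syllable spectrograms for similarity scoring
#'
#' Each syllable's audio is amplitude normalized, clipped or zero-padded to
#' a uniform duration of 180 ms, and transformed to a dB spectrogram from
#' which frequency rows below 2 kHz and above 6 kHz are discarded.
#'
#' @param recs Named list of [song_rec]s (or a single one).
#' @param segs A labelled [segment_table].
#' @param duration Uniform syllable duration in seconds (default 0.180).
#' @param f_lo,f_hi Retained frequency band in Hz.
#' @param window_len,hop STFT parameters in samples.
#' @param downsample Optional `c(n_freq, n_time)` target; when given, each
#'   spectrogram is block-averaged down to this shape (the desk-scale input
#'   used for embedder training).
#' @return A `syllable_spectrogram_set` whose `segments` keep labels.
#' @export
prep_similarity_spectrograms <- function(recs, segs, duration = 0.180,
                                         f_lo = 2000, f_hi = 6000,
                                         window_len = 512, hop = 128,
                                         downsample = NULL) {
  if (inherits(recs, "song_rec")) {
    recs <- stats::setNames(list(recs), recs$source_id)
  }
  miss <- setdiff(unique(segs$file), names(recs))
  if (length(miss)) {
    stop("no recording supplied for file(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  floor_db <- -100
  vecs <- vector("list", nrow(segs))
  dims <- NULL
  for (i in seq_len(nrow(segs))) {
    r <- recs[[segs$file[i]]]
    n_target <- round(duration * r$rate)
    i0 <- max(1L, floor(segs$onset[i] * r$rate) + 1L)
    i1 <- min(length(r$samples), ceiling(segs$offset[i] * r$rate))
    x <- r$samples[i0:i1]
    peak <- max(abs(x))
    if (peak > 0) x <- x / peak
    if (length(x) >= n_target) {
      x <- x[seq_len(n_target)]
    } else {
      x <- c(x, numeric(n_target - length(x)))
    }
    sp <- make_spectrogram(song_rec(x, r$rate, segs$file[i]),
                           window_len = window_len, hop = hop)
    keep <- sp$freqs >= f_lo & sp$freqs <= f_hi
    v <- sp$values[keep, , drop = FALSE]
    v[v < floor_db] <- floor_db
    if (!is.null(downsample)) v <- .block_mean(v, downsample)
    if (is.null(dims)) dims <- dim(v)
    vecs[[i]] <- as.numeric(v)
  }
  structure(list(vectors = do.call(rbind, vecs), segments = segs,
                 n_freq = dims[1], n_time = dims[2]),
            class = "syllable_spectrogram_set")
}

# block-average a matrix down to target dims (simple area interpolation)
.block_mean <- function(v, target) {
  out <- matrix(0, target[1], target[2])
  ri <- as.integer(cut(seq_len(nrow(v)), target[1], labels = FALSE))
  ci <- as.integer(cut(seq_len(ncol(v)), target[2], labels = FALSE))
  for (i in seq_len(target[1])) {
    rows <- ri == i
    for (j in seq_len(target[2])) {
      out[i, j] <- mean(v[rows, ci == j])
    }
  }
  out
}

#' Earth Mover's Distance between embedding sets
#'
#' Exact optimal-transport distance between the two empirical distributions
#' with Euclidean ground metric and uniform weights, computed by the
#' package's min-cost-flow solver. On the unit 8-sphere of the triplet
#' embedder the distance between two point masses at orthogonal positions
#' is `sqrt(2)` (~1.41), the maximum for point-mass distributions under
#' that constraint.
#'
#' @param a,b Numeric matrices of embeddings (rows = syllables).
#' @return Single non-negative numeric.
#' @export
emd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) >= 1L, nrow(b) >= 1L, ncol(a) == ncol(b))
  cost <- .cross_dist(a, b)
  .emd_transport(cost)
}

.cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Maximum Mean Discrepancy between embedding sets
#'
#' Gaussian-RBF MMD with bandwidth `sigma` equal to half the median
#' pairwise distance among up to 1000 embeddings sampled from
#' `bandwidth_ref` (default: the pooled inputs). The biased estimator
#' including diagonal terms is used; the reported value is
#' `sqrt(max(MMD^2, 0))`.
#'
#' @param a,b Numeric matrices of embeddings.
#' @param bandwidth_ref Reference embeddings for the bandwidth heuristic.
#' @param sigma Bandwidth override (skips the heuristic).
#' @param max_ref Sample cap for the bandwidth heuristic.
#' @return Single non-negative numeric.
#' @export
mmd <- function(a, b, bandwidth_ref = NULL, sigma = NULL, max_ref = 1000L) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) >= 1L, nrow(b) >= 1L, ncol(a) == ncol(b))
  if (is.null(sigma)) {
    ref <- if (is.null(bandwidth_ref)) rbind(a, b) else as.matrix(bandwidth_ref)
    if (nrow(ref) > max_ref) ref <- ref[sample.int(nrow(ref), max_ref), , drop = FALSE]
    if (nrow(ref) < 2L) stop("bandwidth reference needs >= 2 points", call. = FALSE)
    pd <- .cross_dist(ref, ref)
    sigma <- 0.5 * stats::median(pd[upper.tri(pd)])
    if (sigma <= 0) {
      stop("degenerate bandwidth (all reference embeddings identical); ",
           "supply sigma explicitly", call. = FALSE)
    }
  }
  k <- function(x, y) exp(-.cross_dist(x, y)^2 / (2 * sigma^2))
  m2 <- mean(k(a, a)) + mean(k(b, b)) - 2 * mean(k(a, b))
  sqrt(max(m2, 0))
}

#' Compare two syllable pools
#'
#' Implements the sampling protocols for repertoire comparisons. For
#' `kind = "self"` the pool is compared against itself: with fewer than
#' `split_limit` syllables it is randomly split in half, otherwise two
#' disjoint samples of `sample_n` syllables are drawn. For every other
#' comparison type, up to `cross_max` syllables are sampled from each pool.
#' Both EMD and MMD are computed; the sampling seed is recorded in the
#' report.
#'
#' @param a,b Embedding matrices (rows = syllables); `b` is ignored for
#'   `kind = "self"`.
#' @param kind One of `"self"`, `"tutor"`, `"sibling"`, `"unrelated"`,
#'   `"developmental"`.
#' @param seed Integer sampling seed (recorded in the report).
#' @param split_limit,sample_n,cross_max Protocol sizes (defaults 4000,
#'   2000, 4000; reduce for desk-scale work).
#' @param bandwidth_ref Passed to [mmd()].
#' @return List of class `similarity_report`: `kind`, `emd`, `mmd`, `n_a`,
#'   `n_b`, `seed`.
#' @export
compare_birds <- function(a, b = NULL,
                          kind = c("self", "tutor", "sibling", "unrelated",
                                   "developmental"),
                          seed = 1L, split_limit = 4000L, sample_n = 2000L,
                          cross_max = 4000L, bandwidth_ref = NULL) {
  kind <- match.arg(kind)
  a <- as.matrix(a)
  set.seed(as.integer(seed))
  if (kind == "self") {
    n <- nrow(a)
    if (n < 4L) stop("self-comparison needs at least 4 syllables", call. = FALSE)
    if (n < split_limit) {
      half <- sample.int(n, n %/% 2L)
      sa <- a[half, , drop = FALSE]
      sb <- a[setdiff(seq_len(n), half), , drop = FALSE]
    } else {
      pick <- sample.int(n, 2L * sample_n)
      sa <- a[pick[seq_len(sample_n)], , drop = FALSE]
      sb <- a[pick[sample_n + seq_len(sample_n)], , drop = FALSE]
    }
  } else {
    stopifnot(!is.null(b))
    b <- as.matrix(b)
    # seed is reset per side: identical pools under one seed draw
    # identical samples (and so compare as identical)
    set.seed(as.integer(seed))
    sa <- if (nrow(a) > cross_max) a[sample.int(nrow(a), cross_max), , drop = FALSE] else a
    set.seed(as.integer(seed))
    sb <- if (nrow(b) > cross_max) b[sample.int(nrow(b), cross_max), , drop = FALSE] else b
  }
  structure(list(kind = kind,
                 emd = emd(sa, sb),
                 mmd = mmd(sa, sb, bandwidth_ref = bandwidth_ref),
                 n_a = nrow(sa), n_b = nrow(sb), seed = as.integer(seed)),
            class = "similarity_report")
}

#' Contrast indices
#'
#' `contrast_index`: `|self - cross| / (self + cross)` where `self` is the
#' bird-vs-itself dissimilarity and `cross` the mean dissimilarity to three
#' unrelated birds. `tutor_contrast_index` substitutes the pupil-vs-tutor
#' dissimilarity for the self term. Values near 1 indicate a scorer that
#' cleanly separates same/tutored comparisons from unrelated ones.
#'
#' @param self_d,tutor_d,cross_d Dissimilarity values; `cross_d` is the
#'   mean over unrelated comparisons. The denominator must be positive.
#' @return Single numeric in `[0, 1]`.
#' @export
contrast_index <- function(self_d, cross_d) {
  if (self_d + cross_d <= 0) stop("zero denominator in contrast index",
                                  call. = FALSE)
  abs((self_d - cross_d) / (self_d + cross_d))
}

#' @rdname contrast_index
#' @export
tutor_contrast_index <- function(tutor_d, cross_d) {
  if (tutor_d + cross_d <= 0) stop("zero denominator in tutor contrast index",
                                   call. = FALSE)
  abs((tutor_d - cross_d) / (tutor_d + cross_d))
}
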