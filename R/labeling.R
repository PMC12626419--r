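#' Standardized per-syllable spectrograms for labeling
#'
#' Each recording is bandpass filtered (500 Hz - 15 kHz, upper edge clamped
#' below Nyquist when needed), each syllable's samples are extracted and
#' amplitude normalized independently, and an STFT (window 512, hop 128) is
#' computed and dB-scaled per syllable. Spectrograms are clipped at
#' `max_dur` seconds (a generous bound that only truncates segmentation
#' errors), padded with the dB floor to the duration of the longest
#' syllable in the set, and flattened into rows of one matrix.
#'
#' @param recs Named list of [song_rec]s (names = file ids) or a single
#'   `song_rec`.
#' @param segs A [segment_table]; all segments must lie inside their
#'   recordings.
#' @param f_lo,f_hi Bandpass edges in Hz.
#' @param window_len,hop STFT parameters in samples.
#' @param max_dur Maximum represented syllable duration in seconds
#'   (default 0.870).
#' @param dynamic_range Spectrogram dynamic range in dB: values more than
#'   this far below the per-syllable maximum are clamped to the floor.
#'   Limiting the range keeps the harmonic structure that identifies a
#'   type dominant over the silent padding that encodes its duration.
#' @return Object of class `syllable_spectrogram_set`: `vectors` (matrix,
#'   one flattened spectrogram per row), `segments` (the input rows),
#'   `n_freq`, `n_time`.
#' @export
prepare_syllable_spectrograms <- function(recs, segs, f_lo = 500,
                                          f_hi = 15000, window_len = 512,
                                          hop = 128, max_dur = 0.870,
                                          dynamic_range = 40) {
  if (inherits(recs, "song_rec")) {
    recs <- stats::setNames(list(recs), recs$source_id)
  }
  miss <- setdiff(unique(segs$file), names(recs))
  if (length(miss)) {
    stop("no recording supplied for file(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  filtered <- lapply(recs, function(r) {
    hi <- min(f_hi, 0.99 * r$rate / 2)
    bandpass(r, f_lo, hi)
  })
  floor_db <- -abs(dynamic_range)
  specs <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    r <- filtered[[segs$file[i]]]
    i0 <- floor(segs$onset[i] * r$rate) + 1L
    i1 <- ceiling(segs$offset[i] * r$rate)
    if (i0 < 1L || i1 > length(r$samples)) {
      stop("segment at row ", i, " lies outside its recording", call. = FALSE)
    }
    x <- r$samples[i0:min(i1, i0 + round(max_dur * r$rate) - 1L)]
    peak <- max(abs(x))
    if (peak > 0) x <- x / peak
    if (length(x) < window_len) x <- c(x, numeric(window_len - length(x)))
    sp <- make_spectrogram(song_rec(x, r$rate, segs$file[i]),
                           window_len = window_len, hop = hop)
    v <- sp$values
    v[v < floor_db] <- floor_db
    specs[[i]] <- v
  }
  n_freq <- nrow(specs[[1]])
  n_time <- max(vapply(specs, ncol, integer(1)))
  vectors <- t(vapply(specs, function(v) {
    if (ncol(v) < n_time) {
      v <- cbind(v, matrix(floor_db, n_freq, n_time - ncol(v)))
    }
    as.numeric(v)
  }, numeric(n_freq * n_time)))
  structure(list(vectors = vectors, segments = segs,
                 n_freq = n_freq, n_time = n_time),
            class = "syllable_spectrogram_set")
}

#' Embed syllable spectrograms in two dimensions
#'
#' Runs the package's [umap_embed()] on the flattened syllable spectrograms
#' with one shared, documented parameter set: 2 output dimensions,
#' `min_dist = 0`, and a neighbourhood of half the syllable count (capped
#' at 100). The wide neighbourhood keeps renditions of one syllable type
#' connected across the discrete duration modes produced by frame
#' quantization; `min_dist = 0` suits density-based clustering downstream.
#' Deterministic given `seed`.
#'
#' @param specs A `syllable_spectrogram_set` with at least 10 syllables.
#' @param seed Integer seed.
#' @param ... Overrides passed to [umap_embed()].
#' @return Matrix `n x 2` of embedding coordinates.
#' @export
embed_umap <- function(specs, seed = 42L, n_neighbors = NULL, ...) {
  stopifnot(inherits(specs, "syllable_spectrogram_set"))
  n <- nrow(specs$vectors)
  if (n < 10L) {
    stop("need at least 10 syllables to embed (got ", n, ")", call. = FALSE)
  }
  if (is.null(n_neighbors)) n_neighbors <- max(30L, min(100L, round(n / 2)))
  umap_embed(specs$vectors, n_components = 2L, seed = seed,
             n_neighbors = n_neighbors, ...)
}

#' Cluster an embedding into syllable labels
#'
#' Applies the package's [hdbscan_cluster()] with one shared hyperparameter
#' set for all birds; points left unassigned carry the reserved `"noise"`
#' token.
#'
#' @param emb Embedding matrix from [embed_umap()].
#' @param ... Overrides passed to [hdbscan_cluster()].
#' @return Character label vector with attribute `n_clusters`.
#' @export
cluster_hdbscan <- function(emb, ...) {
  hdbscan_cluster(emb, ...)
}

#' Align predicted labels to reference annotations
#'
#' Onsets are matched one-to-one per file within `tol` seconds (see
#' [match_events()]). Matched pairs contribute their (reference, predicted)
#' labels; unmatched predictions are assigned the reserved reference
#' category `"x"`, and unmatched references the reserved cluster `"1000"`.
#'
#' @param ref,pred Labelled [segment_table]s.
#' @param tol Matching tolerance in seconds (default 0.1).
#' @return Data frame with columns `ref_label`, `cluster`.
#' @export
align_labels <- function(ref, pred, tol = 0.1) {
  out <- list()
  for (f in union(unique(ref$file), unique(pred$file))) {
    r <- ref[ref$file == f, , drop = FALSE]
    p <- pred[pred$file == f, , drop = FALSE]
    m <- match_events(r$onset, p$onset, tol)
    ri <- match(m$pairs$ref, r$onset)
    pi <- match(m$pairs$pred, p$onset)
    if (length(ri)) {
      out[[length(out) + 1L]] <- data.frame(ref_label = r$label[ri],
                                            cluster = p$label[pi])
    }
    fp <- setdiff(seq_len(nrow(p)), pi)
    if (length(fp)) {
      out[[length(out) + 1L]] <- data.frame(ref_label = "x",
                                            cluster = p$label[fp])
    }
    fn <- setdiff(seq_len(nrow(r)), ri)
    if (length(fn)) {
      out[[length(out) + 1L]] <- data.frame(ref_label = r$label[fn],
                                            cluster = "1000")
    }
  }
  if (length(out) == 0L) return(data.frame(ref_label = character(),
                                           cluster = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Homogeneity, completeness and v-measure of a clustering
#'
#' From the confusion matrix of aligned (reference label, cluster) pairs:
#' `homogeneity = 1 - H(ref | cluster) / H(ref)` (syllables sharing a
#' cluster share a reference label), `completeness = 1 - H(cluster | ref) /
#' H(cluster)` (syllables sharing a reference label share a cluster), and
#' the v-measure is their harmonic mean. Degenerate single-class cases
#' (0/0) are defined as 1. Entropies use the natural log, which cancels in
#' the ratios.
#'
#' @param pairs Data frame with columns `ref_label` and `cluster` (from
#'   [align_labels()]), or a confusion matrix of counts
#'   (clusters x reference labels).
#' @return List of class `cluster_eval`: `confusion`, `homogeneity`,
#'   `completeness`, `v_measure`.
#' @export
cluster_eval <- function(pairs) {
  conf <- if (is.matrix(pairs)) {
    pairs
  } else {
    stopifnot(nrow(pairs) >= 1L)
    unclass(table(pairs$cluster, pairs$ref_label))
  }
  n <- sum(conf)
  stopifnot(n > 0)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  h_ref <- ent(colSums(conf) / n)
  h_clu <- ent(rowSums(conf) / n)
  # H(ref | cluster) = sum_c P(c) H(ref | C = c)
  h_ref_given_clu <- sum(apply(conf, 1, function(row) {
    s <- sum(row)
    if (s == 0) 0 else s / n * ent(row / s)
  }))
  h_clu_given_ref <- sum(apply(conf, 2, function(col) {
    s <- sum(col)
    if (s == 0) 0 else s / n * ent(col / s)
  }))
  hom <- if (h_ref > 0) 1 - h_ref_given_clu / h_ref else 1
  com <- if (h_clu > 0) 1 - h_clu_given_ref / h_clu else 1
  v <- if (hom + com > 0) 2 * hom * com / (hom + com) else 0
  structure(list(confusion = conf, homogeneity = hom, completeness = com,
                 v_measure = v),
            class = "cluster_eval")
}

#' Labeling stability across embedding seeds
#'
#' Re-embeds and re-clusters the same syllable set under each seed and
#' scores the result against reference labels (same syllables, so the
#' confusion matrix is direct), summarizing the dispersion of the
#' v-measure due to embedding stochasticity.
#'
#' @param specs A `syllable_spectrogram_set`.
#' @param seeds Integer vector of at least 2 seeds.
#' @param ref_labels Character vector of reference labels, one per
#'   syllable in `specs`.
#' @param ... Passed to [embed_umap()] / [cluster_hdbscan()].
#' @return List: `per_seed` (data.frame seed, v_measure), `sd_v`.
#' @export
stability_over_seeds <- function(specs, seeds, ref_labels, ...) {
  stopifnot(length(seeds) >= 2L,
            length(ref_labels) == nrow(specs$vectors))
  vs <- vapply(seeds, function(s) {
    emb <- embed_umap(specs, seed = s, ...)
    labs <- cluster_hdbscan(emb)
    cluster_eval(unclass(table(labs, ref_labels)))$v_measure
  }, numeric(1))
  list(per_seed = data.frame(seed = seeds, v_measure = vs),
       sd_v = stats::sd(vs))
}
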