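# Shared fixtures, generated once per test run and memoized. All fixtures
# come from the package's own synthetic song generator under fixed seeds.

.fx_env <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (!exists(name, envir = .fx_env)) assign(name, build(), envir = .fx_env)
  get(name, envir = .fx_env)
}

# small adult dataset + amplitude segmentation of it
fx_adult <- function() fx("adult", function() {
  out <- render_song(synth_preset("adult", n_files = 4, bouts_per_file = 3,
                                  seed = 7))
  out$traces <- lapply(out$recs, function(r) {
    compute_rmse_trace(bandpass(r, 200, 9000))
  })
  out$pred <- do.call(rbind, lapply(out$traces, segment_amplitude,
                                    onset_thr = 0.04, offset_thr = 0.05))
  out
})

# labeled adult dataset for the labeling stage (truth labels, spectrograms)
fx_labeling <- function() fx("labeling", function() {
  out <- render_song(synth_preset("adult", n_files = 8, bouts_per_file = 3,
                                  seed = 5))
  out$truth <- out$truth[out$truth$label != "noise", ]
  class(out$truth) <- c("segment_table", "data.frame")
  out$specs <- prepare_syllable_spectrograms(out$recs, out$truth)
  out
})

# adult/juvenile pair for paired timing contrasts (same seed family)
fx_regimes <- function() fx("regimes", function() {
  list(adult = render_song(synth_preset("adult", n_files = 12,
                                        bouts_per_file = 4, seed = 3)),
       juvenile = render_song(synth_preset("juvenile", n_files = 12,
                                           bouts_per_file = 4, seed = 3)))
})

# labelled segment table with controlled gaps, for syntax tests:
# per file, labels and the silent gap (s) after each syllable
make_label_table <- function(seqs, gaps, dur = 0.05) {
  rows <- list()
  for (f in names(seqs)) {
    labs <- seqs[[f]]
    g <- gaps[[f]]
    onset <- 0.3
    for (i in seq_along(labs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        file = f, onset = onset, offset = onset + dur, label = labs[i])
      onset <- onset + dur + if (i <= length(g)) g[i] else 0.5
    }
  }
  df <- do.call(rbind, rows)
  segment_table(df$file, df$onset, df$offset, df$label)
}

# transition_matrix object built directly from counts (test construction)
make_tm <- function(counts, pi = NULL, silence_token = "silence") {
  states <- rownames(counts)
  rs <- rowSums(counts)
  probs <- counts
  probs[rs > 0, ] <- counts[rs > 0, , drop = FALSE] / rs[rs > 0]
  probs[rs == 0, ] <- NA_real_
  if (is.null(pi)) {
    occ <- rowSums(counts) + colSums(counts)
    pi <- occ / sum(occ)
  }
  structure(list(states = states, counts = counts, probs = probs,
                 pi = stats::setNames(pi, states),
                 silence_token = silence_token),
            class = "transition_matrix")
}

# brute-force optimal one-to-one matching oracle (maximum matches within tol)
brute_force_match <- function(ref, pred, tol) {
  best <- 0L
  recurse <- function(i, used, count) {
    if (i > length(ref)) {
      best <<- max(best, count)
      return()
    }
    recurse(i + 1L, used, count)          # leave ref i unmatched
    for (j in seq_along(pred)) {
      if (!used[j] && abs(ref[i] - pred[j]) <= tol) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(pred)), 0L)
  best
}

# direct-entropy clustering-score oracle on a confusion matrix
entropy_scores_oracle <- function(conf) {
  n <- sum(conf)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  h_ref <- H(colSums(conf) / n)
  h_clu <- H(rowSums(conf) / n)
  h_rc <- 0; h_cr <- 0
  for (i in seq_len(nrow(conf))) {
    s <- sum(conf[i, ]); if (s > 0) h_rc <- h_rc + s / n * H(conf[i, ] / s)
  }
  for (j in seq_len(ncol(conf))) {
    s <- sum(conf[, j]); if (s > 0) h_cr <- h_cr + s / n * H(conf[, j] / s)
  }
  hom <- if (h_ref > 0) 1 - h_rc / h_ref else 1
  com <- if (h_clu > 0) 1 - h_cr / h_clu else 1
  v <- if (hom + com > 0) 2 * hom * com / (hom + com) else 0
  list(homogeneity = hom, completeness = com, v_measure = v)
}

# 1-D uniform-weight EMD closed form: area between empirical CDFs
emd_1d_oracle <- function(x, y) {
  g <- sort(c(x, y))
  mids <- (g[-1] + g[-length(g)]) / 2
  sum(abs(stats::ecdf(x)(mids) - stats::ecdf(y)(mids)) * diff(g))
}
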