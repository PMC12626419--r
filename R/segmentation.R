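#' Construct and validate a segment table
#'
#' A segment table is the package's tabular interchange format for syllable
#' segmentations: one row per segment with the source file id, onset and
#' offset in seconds, and an optional label. External segmenter outputs
#' (e.g. neural voice-activity detectors) enter the pipeline as these tables.
#'
#' @param file Character vector of source ids.
#' @param onset,offset Numeric vectors, seconds; `onset < offset` rowwise.
#' @param label Optional character vector of syllable labels (`""` = none).
#' @return A `data.frame` of class `segment_table`, sorted by (file, onset).
#' @export
segment_table <- function(file, onset, offset, label = NULL) {
  if (is.null(label)) label <- rep("", length(onset))
  df <- data.frame(file = as.character(file), onset = as.numeric(onset),
                   offset = as.numeric(offset), label = as.character(label),
                   stringsAsFactors = FALSE)
  bad <- which(!(df$onset < df$offset))
  if (length(bad)) {
    stop("segment_table: onset >= offset at row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$file, df$onset), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("segment_table", "data.frame")
  df
}

#' Read / write segment tables as CSV
#'
#' CSV with header columns `onset,offset,label,file`; times in seconds at
#' 6-decimal precision (round-trip lossless at that precision). A missing
#' `label` column yields empty labels.
#'
#' @param path CSV path.
#' @return `read_segment_table`: a [segment_table].
#' @export
read_segment_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, check.names = TRUE)
  need <- c("onset", "offset", "file")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("segment table ", path, " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"label" %in% names(df)) df$label <- ""
  df$label[is.na(df$label)] <- ""
  ok <- !is.na(df$onset) & !is.na(df$offset)
  if (any(!ok)) {
    stop("segment table ", path, ": malformed numeric value at row(s) ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  }
  bad <- which(!(df$onset < df$offset))
  if (length(bad)) {
    stop("segment table ", path, ": onset >= offset at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  segment_table(df$file, df$onset, df$offset, df$label)
}

#' @rdname read_segment_table
#' @param table A [segment_table].
#' @export
write_segment_table <- function(table, path) {
  out <- data.frame(onset = sprintf("%.6f", table$onset),
                    offset = sprintf("%.6f", table$offset),
                    label = table$label, file = table$file)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Amplitude-derivative syllable segmentation
#'
#' Onsets are positive crossings of `onset_thr` by the first difference of
#' the normalized RMSE trace. Segmentation is onset-to-onset: each segment
#' runs to the next onset (so it includes the syllable plus the silent gap
#' that follows it), unless no further onset occurs within `max_onset_gap`
#' seconds, in which case the offset is the first downward crossing of
#' `offset_thr` by the RMSE itself after the onset (falling back to the end
#' of the trace). Degenerate segments shorter than `min_frames` RMSE frames
#' are discarded.
#'
#' @param trace An `amp_trace` from [compute_rmse_trace()] (normalized).
#' @param onset_thr Threshold on the RMSE first difference (per frame).
#' @param offset_thr Threshold on normalized RMSE for trailing offsets.
#' With `refine = TRUE` (default) each detected onset timestamp is refined
#' to sub-frame precision: because the RMSE frames are centered, the
#' windowed signal *energy* of a sharp onset reaches half of its local
#' plateau exactly at the onset time, so the onset is placed at the
#' linearly interpolated half-rise crossing of the squared RMSE around the
#' detection frame. Detection itself (which crossings count) is unaffected.
#'
#' @param max_onset_gap Seconds; onset-to-onset rule horizon (default 0.3).
#' @param min_frames Minimum segment length in frames (default 2).
#' @param refine Refine onset timestamps to the sub-frame half-rise point.
#' @return A [segment_table] (no labels).
#' @export
segment_amplitude <- function(trace, onset_thr, offset_thr,
                              max_onset_gap = 0.3, min_frames = 2L,
                              refine = TRUE) {
  stopifnot(inherits(trace, "amp_trace"))
  r <- trace$rmse
  if (length(r) < 2L) return(segment_table(character(), numeric(), numeric()))
  d <- diff(r)
  # positive crossing: derivative moves from <= thr to > thr
  up <- which(d[-1] > onset_thr & d[-length(d)] <= onset_thr) + 1L
  if (length(d) >= 1L && d[1] > onset_thr) up <- c(1L, up)
  if (length(up) == 0L) return(segment_table(character(), numeric(), numeric()))
  frame_t <- trace$hop / trace$rate
  onset_frames <- up          # derivative index i = change into frame i+1; frame i is 0-based i
  onsets <- onset_frames * frame_t
  if (refine) onsets <- .refine_onsets(trace, onsets)
  n <- length(onsets)
  offsets <- numeric(n)
  for (k in seq_len(n)) {
    if (k < n && (onsets[k + 1] - onsets[k]) < max_onset_gap) {
      offsets[k] <- onsets[k + 1]
    } else {
      after <- seq(onset_frames[k] + 1L, length(r))
      dn <- which(r[after][-1] < offset_thr & r[after][-length(after)] >= offset_thr)
      if (length(dn)) {
        offsets[k] <- (onset_frames[k] + dn[1]) * frame_t
      } else {
        offsets[k] <- (length(r) - 1L) * frame_t
      }
    }
  }
  keep <- (offsets - onsets) >= (min_frames * frame_t) - 1e-12
  if (!any(keep)) return(segment_table(character(), numeric(), numeric()))
  segment_table(rep(trace$source_id, sum(keep)), onsets[keep], offsets[keep])
}

# Sub-frame onset refinement on the fine energy trace (squared fine RMSE).
# With centered windows, the windowed energy of a sharp onset reaches half
# of its local plateau exactly at the onset time, so the onset estimate is
# the linearly interpolated half-rise crossing of the fine energy in a
# short neighbourhood of the detected (coarse) onset.
.refine_onsets <- function(trace, onsets, window_s = 0.030) {
  if (is.null(trace$fine_rmse)) return(onsets)
  e <- trace$fine_rmse^2
  ft <- trace$fine_hop / trace$rate
  n <- length(e)
  vapply(onsets, function(t0) {
    i <- min(n, max(1L, round(t0 / ft) + 1L))
    w <- max(2L, round(window_s / ft))
    lo_rng <- max(1L, i - w):i
    hi_rng <- i:min(n, i + w)
    lo <- lo_rng[which.min(e[lo_rng])]
    hi <- hi_rng[which.max(e[hi_rng])]
    base <- e[lo]; peak <- e[hi]
    if (hi <= lo || peak <= base) return(t0)
    half <- (base + peak) / 2
    j <- lo
    while (j < hi && e[j + 1L] < half) j <- j + 1L
    if (e[j + 1L] <= e[j]) return(t0)
    (j - 1L + (half - e[j]) / (e[j + 1L] - e[j])) * ft
  }, numeric(1))
}

#' One-to-one event matching within a tolerance
#'
#' Matches reference to predicted event times so that each event on either
#' side participates in at most one pair and every matched pair differs by
#' at most `tol` seconds. Because events live on a line, some maximum
#' matching is non-crossing, so an exact dynamic program over the two
#' sorted lists finds the maximum number of pairs (ties broken by the
#' smallest total absolute time difference).
#'
#' @param ref,pred Sorted numeric vectors of event times (seconds).
#' @param tol Matching tolerance in seconds.
#' @return An object of class `match_result`: `pairs` (data.frame with
#'   `ref`, `pred`, `delta = pred - ref`), `tp`, `fp`, `fn`.
#' @export
match_events <- function(ref, pred, tol) {
  ref <- sort(as.numeric(ref)); pred <- sort(as.numeric(pred))
  nr <- length(ref); np <- length(pred)
  pairs <- data.frame(ref = numeric(), pred = numeric(), delta = numeric())
  if (nr > 0L && np > 0L) {
    # DP over sorted lists: count[i+1, j+1] = max matches using ref[1..i],
    # pred[1..j]; cost breaks ties by total |delta|
    count <- matrix(0L, nr + 1L, np + 1L)
    cost <- matrix(0, nr + 1L, np + 1L)
    for (i in seq_len(nr)) {
      for (j in seq_len(np)) {
        cnt <- count[i, j + 1L]; cst <- cost[i, j + 1L]
        if (count[i + 1L, j] > cnt ||
            (count[i + 1L, j] == cnt && cost[i + 1L, j] < cst)) {
          cnt <- count[i + 1L, j]; cst <- cost[i + 1L, j]
        }
        d <- abs(ref[i] - pred[j])
        if (d <= tol) {
          mc <- count[i, j] + 1L; ms <- cost[i, j] + d
          if (mc > cnt || (mc == cnt && ms < cst)) {
            cnt <- mc; cst <- ms
          }
        }
        count[i + 1L, j + 1L] <- cnt
        cost[i + 1L, j + 1L] <- cst
      }
    }
    ri <- integer(0); pj <- integer(0)
    i <- nr; j <- np
    while (i > 0L && j > 0L) {
      d <- abs(ref[i] - pred[j])
      if (d <= tol && count[i + 1L, j + 1L] == count[i, j] + 1L &&
          abs(cost[i + 1L, j + 1L] - (cost[i, j] + d)) < 1e-12) {
        ri <- c(i, ri); pj <- c(j, pj); i <- i - 1L; j <- j - 1L
      } else if (count[i, j + 1L] == count[i + 1L, j + 1L] &&
                 abs(cost[i, j + 1L] - cost[i + 1L, j + 1L]) < 1e-12) {
        i <- i - 1L
      } else {
        j <- j - 1L
      }
    }
    if (length(ri)) {
      pairs <- data.frame(ref = ref[ri], pred = pred[pj],
                          delta = pred[pj] - ref[ri])
    }
  }
  structure(list(pairs = pairs, tp = nrow(pairs),
                 fp = np - nrow(pairs), fn = nr - nrow(pairs)),
            class = "match_result")
}

#' Precision, recall and F1 from a match result
#'
#' `F1 = TP / (TP + (FP + FN) / 2)`; any 0/0 is defined as 0.
#'
#' @param match A `match_result` from [match_events()], or a list with
#'   `tp`, `fp`, `fn` counts.
#' @return Named list with `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
seg_f1 <- function(match) {
  tp <- match$tp; fp <- match$fp; fn <- match$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  div0 <- function(a, b) if (b > 0) a / b else 0
  list(precision = div0(tp, tp + fp),
       recall = div0(tp, tp + fn),
       f1 = div0(tp, tp + 0.5 * (fp + fn)),
       tp = tp, fp = fp, fn = fn)
}

#' Signed time differences of matched events
#'
#' @param match A `match_result`.
#' @return List with `deltas` (seconds, `pred - ref`) and
#'   `median_abs` (median absolute delta).
#' @export
time_deltas <- function(match) {
  d <- match$pairs$delta
  list(deltas = d,
       median_abs = if (length(d)) stats::median(abs(d)) else NA_real_)
}

#' Onset and offset segmentation metrics against a reference
#'
#' Convenience wrapper computing one-to-one onset matching at a 10 ms
#' tolerance and offset matching at 20 ms, per file, and pooling the counts.
#'
#' @param ref,pred [segment_table]s.
#' @param onset_tol,offset_tol Tolerances in seconds.
#' @return List with `onset` and `offset` metric lists (see [seg_f1()]) and
#'   the pooled `onset_match`/`offset_match` delta vectors.
#' @export
seg_metrics <- function(ref, pred, onset_tol = 0.010, offset_tol = 0.020) {
  files <- union(unique(ref$file), unique(pred$file))
  tot <- function(field, tol) {
    tp <- fp <- fn <- 0L; deltas <- numeric()
    for (f in files) {
      m <- match_events(ref[[field]][ref$file == f],
                        pred[[field]][pred$file == f], tol)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
      deltas <- c(deltas, m$pairs$delta)
    }
    c(seg_f1(list(tp = tp, fp = fp, fn = fn)), list(deltas = deltas))
  }
  list(onset = tot("onset", onset_tol), offset = tot("offset", offset_tol))
}

#' Shared segmentation-threshold optimization across birds
#'
#' Evaluates every candidate threshold pair on every bird and returns the
#' pair maximizing the mean onset-F1 across birds (ties broken by the lower
#' onset threshold, then lower offset threshold).
#'
#' @param traces Named list (one element per bird) of lists of `amp_trace`s.
#' @param refs Named list (same names) of reference [segment_table]s.
#' @param grid Data frame with columns `onset_thr`, `offset_thr`.
#' @param onset_tol Onset matching tolerance in seconds.
#' @return List: `onset_thr`, `offset_thr`, `mean_f1`, and the evaluated
#'   `grid` with a `mean_f1` column.
#' @export
optimize_thresholds <- function(traces, refs, grid, onset_tol = 0.010) {
  if (is.null(dim(grid)) || nrow(grid) == 0L) {
    stop("grid must be a non-empty data frame of candidate thresholds",
         call. = FALSE)
  }
  stopifnot(all(c("onset_thr", "offset_thr") %in% names(grid)),
            length(traces) >= 1L, identical(sort(names(traces)), sort(names(refs))))
  mean_f1 <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    f1s <- vapply(names(traces), function(bird) {
      pred <- do.call(rbind, lapply(traces[[bird]], function(tr) {
        segment_amplitude(tr, grid$onset_thr[g], grid$offset_thr[g])
      }))
      ref <- refs[[bird]]
      m <- seg_metrics(ref, pred, onset_tol = onset_tol)
      m$onset$f1
    }, numeric(1))
    mean_f1[g] <- mean(f1s)
  }
  ord <- order(-mean_f1, grid$onset_thr, grid$offset_thr)
  best <- ord[1]
  out_grid <- grid
  out_grid$mean_f1 <- mean_f1
  list(onset_thr = grid$onset_thr[best], offset_thr = grid$offset_thr[best],
       mean_f1 = mean_f1[best], grid = out_grid)
}

#' Default threshold grid for [optimize_thresholds()]
#'
#' Evenly spaced onset-threshold candidates over `(0, max_deriv)` crossed
#' with a small set of offset thresholds.
#'
#' @param max_deriv Upper bound for onset-threshold candidates.
#' @param n Number of onset candidates.
#' @param offset_thrs Offset-threshold candidates.
#' @return Data frame with columns `onset_thr`, `offset_thr`.
#' @export
default_threshold_grid <- function(max_deriv = 0.2, n = 10,
                                   offset_thrs = c(0.02, 0.05, 0.1)) {
  cand <- seq(0, max_deriv, length.out = n + 1L)[-1]
  expand.grid(onset_thr = cand, offset_thr = offset_thrs,
              KEEP.OUT.ATTRS = FALSE)
}
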