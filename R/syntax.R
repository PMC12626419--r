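#' Extract song bouts from a labelled segment table
#'
#' A bout is a sequence of at least two syllables separated by silent gaps
#' no longer than `max_gap` seconds. Sequences are split at file boundaries
#' and at longer gaps; isolated single syllables (silence or a file bound on
#' both sides) are dropped, as they likely reflect calls produced outside of
#' song.
#'
#' @param labels A labelled [segment_table].
#' @param max_gap Maximum intra-bout silent gap in seconds (default 0.2).
#' @return An object of class `bout_set`: list with `bouts` (list of
#'   character label vectors) and `meta` (data.frame: file, start onset).
#' @export
extract_bouts <- function(labels, max_gap = 0.2) {
  bouts <- list(); meta_file <- character(); meta_onset <- numeric()
  for (f in unique(labels$file)) {
    sub <- labels[labels$file == f, , drop = FALSE]
    if (nrow(sub) == 0L) next
    gaps <- if (nrow(sub) > 1L) sub$onset[-1] - sub$offset[-nrow(sub)] else numeric()
    grp <- cumsum(c(1L, as.integer(gaps > max_gap)))
    for (gi in unique(grp)) {
      idx <- which(grp == gi)
      if (length(idx) >= 2L) {
        bouts[[length(bouts) + 1L]] <- sub$label[idx]
        meta_file <- c(meta_file, f)
        meta_onset <- c(meta_onset, sub$onset[idx[1]])
      }
    }
  }
  structure(list(bouts = bouts,
                 meta = data.frame(file = meta_file, onset = meta_onset)),
            class = "bout_set")
}

#' Bout raster aligned on a chosen syllable
#'
#' Pads every bout so that the first occurrence of `align_label` falls in
#' the same column, then orders rows so that bouts with identical or similar
#' post-alignment sequences are adjacent (lexicographic sort on the
#' post-alignment sequence, then on the pre-alignment tail).
#'
#' @param bouts A `bout_set`.
#' @param align_label Alignment syllable token; must occur in at least one
#'   bout.
#' @param pad Token used for padding cells (default `""`).
#' @return Character matrix, one row per bout containing `align_label`
#'   (bouts lacking it are appended unaligned at the bottom).
#' @export
make_syntax_raster <- function(bouts, align_label, pad = "") {
  bl <- bouts$bouts
  pos <- vapply(bl, function(b) {
    p <- which(b == align_label)
    if (length(p)) p[1] else NA_integer_
  }, integer(1))
  if (all(is.na(pos))) {
    stop("alignment label '", align_label, "' occurs in no bout", call. = FALSE)
  }
  align_col <- max(pos, na.rm = TRUE)
  lens <- lengths(bl)
  width <- max(ifelse(is.na(pos), lens, align_col + lens - pos))
  row_of <- function(b, p) {
    lead <- if (is.na(p)) 0L else align_col - p
    r <- c(rep(pad, lead), b)
    c(r, rep(pad, width - length(r)))
  }
  m <- t(mapply(row_of, bl, pos))
  # order: aligned bouts first, sorted by post-alignment sequence
  post_key <- vapply(seq_along(bl), function(i) {
    if (is.na(pos[i])) return("~~~")  # sorts last
    paste(bl[[i]][pos[i]:lens[i]], collapse = "\r")
  }, character(1))
  pre_key <- vapply(seq_along(bl), function(i) {
    if (is.na(pos[i]) || pos[i] == 1L) return("")
    paste(rev(bl[[i]][seq_len(pos[i] - 1L)]), collapse = "\r")
  }, character(1))
  m <- m[order(post_key, pre_key), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Syllable transition matrix with a silence state
#'
#' Isolated single syllables are dropped (call rule, see [extract_bouts()]),
#' then silent gaps longer than `max_gap` seconds are inserted as a
#' `"silence"` state between consecutive syllables of a file. Transitions
#' between adjacent states are counted; transitions to and from file bounds
#' are ignored. Row-normalized counts give the conditional probability of
#' the next state given the current one, and the occupancy `pi` is each
#' state's share of all in-scope state occurrences (silence included).
#'
#' @param labels A labelled [segment_table].
#' @param max_gap Silence-state threshold in seconds (default 0.2).
#' @param silence_token Token reserved for the silence state.
#' @return Object of class `transition_matrix`: `states`, `counts`, `probs`,
#'   `pi`, `silence_token`.
#' @export
make_transition_matrix <- function(labels, max_gap = 0.2,
                                   silence_token = "silence") {
  if (any(labels$label == silence_token)) {
    stop("label set already contains the silence token '", silence_token, "'",
         call. = FALSE)
  }
  seqs <- .state_sequences(labels, max_gap, silence_token)
  types <- sort(unique(unlist(lapply(seqs, function(s) s[s != silence_token]))))
  states <- c(types, silence_token)
  n <- length(states)
  counts <- matrix(0, n, n, dimnames = list(states, states))
  occ <- stats::setNames(rep(0, n), states)
  for (s in seqs) {
    if (length(s) == 0L) next
    tab <- table(factor(s, levels = states))
    occ <- occ + as.numeric(tab)
    if (length(s) > 1L) {
      for (i in seq_len(length(s) - 1L)) {
        counts[s[i], s[i + 1L]] <- counts[s[i], s[i + 1L]] + 1
      }
    }
  }
  rs <- rowSums(counts)
  probs <- counts
  nz <- rs > 0
  probs[nz, ] <- counts[nz, , drop = FALSE] / rs[nz]
  probs[!nz, ] <- NA_real_
  pi <- if (sum(occ) > 0) occ / sum(occ) else occ
  structure(list(states = states, counts = counts, probs = probs, pi = pi,
                 silence_token = silence_token),
            class = "transition_matrix")
}

# per-file state sequences: syllables with silence inserted at long gaps,
# isolated singletons removed, file bounds trimmed
.state_sequences <- function(labels, max_gap, silence_token) {
  out <- list()
  for (f in unique(labels$file)) {
    sub <- labels[labels$file == f, , drop = FALSE]
    if (nrow(sub) == 0L) next
    gaps <- if (nrow(sub) > 1L) sub$onset[-1] - sub$offset[-nrow(sub)] else numeric()
    grp <- cumsum(c(1L, as.integer(gaps > max_gap)))
    sizes <- table(grp)
    keep <- as.integer(grp) %in% as.integer(names(sizes)[sizes >= 2L])
    sub <- sub[keep, , drop = FALSE]
    grp <- grp[keep]
    if (nrow(sub) == 0L) next
    s <- character()
    prev_grp <- NULL
    for (i in seq_len(nrow(sub))) {
      if (!is.null(prev_grp) && grp[i] != prev_grp) s <- c(s, silence_token)
      s <- c(s, sub$label[i])
      prev_grp <- grp[i]
    }
    out[[length(out) + 1L]] <- s
  }
  out
}

#' Normalized entropy rate of a transition matrix
#'
#' `raw = -sum_i pi_i sum_k p_ik log2 p_ik`, divided by `log2(N)` where `N`
#' is the number of states of the matrix (syllable types plus one for
#' silence), then clipped to `[0, 1]`. Rows without outgoing transitions are
#' excluded from the sum. A score near 0 means every transition is
#' predictable (stereotyped syntax); 1 is the uniform-transition maximum.
#'
#' @param tm A `transition_matrix`.
#' @return Single numeric in `[0, 1]`.
#' @export
entropy_rate <- function(tm) {
  stopifnot(inherits(tm, "transition_matrix"))
  n_states <- length(tm$states)
  if (n_states <= 1L) {
    stop("entropy rate undefined for a single-state matrix", call. = FALSE)
  }
  raw <- 0
  for (i in seq_len(n_states)) {
    p <- tm$probs[i, ]
    if (all(is.na(p))) next
    nz <- which(p > 0)
    raw <- raw - tm$pi[i] * sum(p[nz] * log2(p[nz]))
  }
  min(max(raw / log2(n_states), 0), 1)
}

#' Repetition-bout statistics per syllable type
#'
#' A repetition bout is a maximal run of one label within a song bout. For
#' the sequence `abcaaabc`, syllable `a` has two repetition bouts, of
#' lengths 1 and 3. Per type the number of runs, mean run length and CV of
#' run length (population s.d. / mean) are returned.
#'
#' @param bouts A `bout_set`.
#' @return Data frame with columns `label`, `n_bouts`, `mean_len`, `cv_len`,
#'   `max_len`.
#' @export
repetition_stats <- function(bouts) {
  stopifnot(inherits(bouts, "bout_set"))
  runs_label <- character(); runs_len <- integer()
  for (b in bouts$bouts) {
    r <- rle(b)
    runs_label <- c(runs_label, r$values)
    runs_len <- c(runs_len, r$lengths)
  }
  if (length(runs_label) == 0L) {
    return(data.frame(label = character(), n_bouts = integer(),
                      mean_len = numeric(), cv_len = numeric(),
                      max_len = integer()))
  }
  out <- do.call(rbind, lapply(sort(unique(runs_label)), function(lab) {
    len <- runs_len[runs_label == lab]
    m <- mean(len)
    data.frame(label = lab, n_bouts = length(len), mean_len = m,
               cv_len = .pop_cv(len), max_len = max(len))
  }))
  rownames(out) <- NULL
  out
}

# population coefficient of variation (s.d. with ddof = 0)
.pop_cv <- function(x) {
  m <- mean(x)
  if (m == 0) return(NA_real_)
  sqrt(mean((x - m)^2)) / m
}

#' Putative introductory notes
#'
#' A syllable type is a putative introductory note if (1) its probability of
#' being transitioned to from silence is within `silence_margin` (absolute)
#' of the type most commonly transitioned to from silence, and (2) it has a
#' single dominant transition to a type other than itself: the largest
#' outgoing probability, renormalized over non-self, non-silence targets,
#' exceeds `dominance`.
#'
#' @param tm A `transition_matrix` containing a silence state.
#' @param silence_margin Absolute tolerance below the top silence-exit
#'   probability (default 0.05).
#' @param dominance Threshold on the renormalized dominant transition
#'   (default 0.5).
#' @return Character vector of tokens (possibly empty).
#' @export
find_intro_notes <- function(tm, silence_margin = 0.05, dominance = 0.5) {
  stopifnot(inherits(tm, "transition_matrix"))
  sil <- tm$silence_token
  if (!sil %in% tm$states) return(character())
  types <- setdiff(tm$states, sil)
  from_sil <- tm$probs[sil, types]
  if (all(is.na(from_sil))) return(character())
  top <- max(from_sil, na.rm = TRUE)
  cand <- types[!is.na(from_sil) & from_sil >= top - silence_margin]
  keep <- vapply(cand, function(tok) {
    p <- tm$probs[tok, ]
    if (all(is.na(p))) return(FALSE)
    targets <- setdiff(types, tok)
    if (length(targets) == 0L) return(FALSE)
    tot <- sum(p[targets], na.rm = TRUE)
    if (tot <= 0) return(FALSE)
    max(p[targets] / tot, na.rm = TRUE) > dominance
  }, logical(1))
  cand[keep]
}

#' Putative calls
#'
#' A non-introductory-note type is a putative call if more than `frac` of
#' its renditions occur in utterances of one or two syllables that are
#' preceded and followed by at least `max_gap` seconds of silence (file
#' bounds count as silence).
#'
#' @param labels A labelled [segment_table].
#' @param intro Tokens already classified as introductory notes.
#' @param max_gap Isolation gap in seconds (default 0.2).
#' @param frac Fraction threshold (default 1/3).
#' @return Character vector of tokens.
#' @export
find_calls <- function(labels, intro = character(), max_gap = 0.2,
                       frac = 1 / 3) {
  total <- stats::setNames(rep(0, 0), character())
  isolated <- total
  for (f in unique(labels$file)) {
    sub <- labels[labels$file == f, , drop = FALSE]
    if (nrow(sub) == 0L) next
    gaps <- if (nrow(sub) > 1L) sub$onset[-1] - sub$offset[-nrow(sub)] else numeric()
    grp <- cumsum(c(1L, as.integer(gaps > max_gap)))
    sizes <- table(grp)
    for (i in seq_len(nrow(sub))) {
      lab <- sub$label[i]
      total[lab] <- ifelse(is.na(total[lab]), 0, total[lab]) + 1
      if (sizes[as.character(grp[i])] <= 2L) {
        isolated[lab] <- ifelse(is.na(isolated[lab]), 0, isolated[lab]) + 1
      }
    }
  }
  toks <- setdiff(names(total), intro)
  toks[vapply(toks, function(tok) {
    iso <- if (tok %in% names(isolated)) isolated[[tok]] else 0
    iso / total[[tok]] > frac
  }, logical(1))]
}

#' Syntax feature bundle
#'
#' Computes the normalized entropy rate plus repetition statistics of the
#' non-intro, non-call syllable type with the highest mean repetition-bout
#' length. The reserved `"noise"` cluster token, putative calls and putative
#' introductory notes are excluded from the repetition summary.
#'
#' @param labels A labelled [segment_table].
#' @param max_gap Bout/silence gap threshold in seconds.
#' @param noise_token Label assigned to unclustered syllables.
#' @return List of class `syntax_features`: `entropy_rate_norm`,
#'   `mean_rep_bout_len`, `cv_rep_bout_len`, `rep_type`, `intro_notes`,
#'   `calls`, `per_type` (full repetition table).
#' @export
syntax_features <- function(labels, max_gap = 0.2, noise_token = "noise") {
  tm <- make_transition_matrix(labels, max_gap = max_gap)
  er <- entropy_rate(tm)
  intro <- find_intro_notes(tm)
  calls <- find_calls(labels, intro, max_gap = max_gap)
  bouts <- extract_bouts(labels, max_gap = max_gap)
  reps <- repetition_stats(bouts)
  eligible <- reps[!(reps$label %in% c(intro, calls, noise_token)), , drop = FALSE]
  if (nrow(eligible) == 0L) {
    sel <- list(mean_len = NA_real_, cv_len = NA_real_, label = NA_character_)
  } else {
    i <- which.max(eligible$mean_len)
    sel <- list(mean_len = eligible$mean_len[i], cv_len = eligible$cv_len[i],
                label = eligible$label[i])
  }
  structure(list(entropy_rate_norm = er,
                 mean_rep_bout_len = sel$mean_len,
                 cv_rep_bout_len = sel$cv_len,
                 rep_type = sel$label,
                 intro_notes = intro, calls = calls, per_type = reps,
                 transition_matrix = tm),
            class = "syntax_features")
}
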