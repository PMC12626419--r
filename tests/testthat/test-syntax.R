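test_that("bout extraction applies the 200 ms gap rule and drops isolated syllables", {
  # gaps of 50, 300, 50 ms between 4 syllables: two 2-syllable bouts
  tab <- make_label_table(list(f1 = c("a", "b", "a", "b")),
                          list(f1 = c(0.05, 0.3, 0.05)))
  b <- extract_bouts(tab)
  expect_length(b$bouts, 2L)
  expect_true(all(lengths(b$bouts) == 2L))

  # one isolated syllable: nothing
  single <- make_label_table(list(f1 = "a"), list(f1 = numeric()))
  expect_length(extract_bouts(single)$bouts, 0L)

  # 10 syllables with sub-200 ms gaps: one bout of 10
  ten <- make_label_table(list(f1 = rep(c("a", "b"), 5)),
                          list(f1 = rep(0.1, 9)))
  b10 <- extract_bouts(ten)
  expect_length(b10$bouts, 1L)
  expect_length(b10$bouts[[1]], 10L)
})

test_that("syntax raster aligns the first alignment syllable across bouts", {
  bouts <- structure(list(bouts = list(c("i", "i", "a", "b"),
                                       c("i", "a", "b")),
                          meta = data.frame(file = c("f", "f"),
                                            onset = c(0, 1))),
                     class = "bout_set")
  m <- make_syntax_raster(bouts, "a")
  cols_a <- apply(m, 1, function(r) which(r == "a")[1])
  expect_equal(cols_a[1], cols_a[2])
  # leading pads differ by one intro note
  expect_equal(sum(m[m[, 1] == "", 1] == ""), 1L)

  one <- structure(list(bouts = list(c("a", "b")),
                        meta = data.frame(file = "f", onset = 0)),
                   class = "bout_set")
  m1 <- make_syntax_raster(one, "a")
  expect_equal(nrow(m1), 1L)
  expect_equal(ncol(m1), 2L)

  same <- structure(list(bouts = list(c("a", "b"), c("a", "b")),
                         meta = data.frame(file = c("f", "f"), onset = 0:1)),
                    class = "bout_set")
  ms <- make_syntax_raster(same, "a")
  expect_equal(ms[1, ], ms[2, ])

  expect_error(make_syntax_raster(one, "z"), "no bout")
})

test_that("transition matrix counts interior transitions and silence states", {
  # a,b,a,b with short gaps, file-bound ends: interior transitions only
  tab <- make_label_table(list(f1 = c("a", "b", "a", "b")),
                          list(f1 = rep(0.05, 3)))
  tm <- make_transition_matrix(tab)
  expect_equal(unname(tm$probs["a", "b"]), 1)
  expect_equal(unname(tm$probs["b", "a"]), 1)
  expect_equal(unname(tm$counts["a", "b"]), 2)
  expect_equal(unname(tm$counts["b", "a"]), 1)
  # silence state exists but is unvisited here
  expect_true("silence" %in% tm$states)
  expect_equal(unname(tm$pi["silence"]), 0)

  # single isolated syllable per file: everything call-filtered away
  lone <- make_label_table(list(f1 = "a", f2 = "a"),
                           list(f1 = numeric(), f2 = numeric()))
  tm0 <- make_transition_matrix(lone)
  expect_equal(sum(tm0$counts), 0)

  # bout then > 200 ms silence then bout: silence entries/exits counted
  tab2 <- make_label_table(list(f1 = c("a", "a", "b", "b")),
                           list(f1 = c(0.05, 0.4, 0.05)))
  tm2 <- make_transition_matrix(tab2)
  expect_equal(unname(tm2$counts["a", "silence"]), 1)
  expect_equal(unname(tm2$counts["silence", "b"]), 1)
  # row sums of probs are 1 for rows with transitions
  rs <- rowSums(tm2$probs, na.rm = TRUE)
  expect_true(all(abs(rs[rowSums(tm2$counts) > 0] - 1) < 1e-12))
  # conservation: a->a, a->silence, silence->b, b->b
  expect_equal(sum(tm2$counts), 4)
})

test_that("entropy rate matches closed forms and is normalized by log2(states)", {
  # deterministic cycle: zero entropy
  det <- make_tm(matrix(c(0, 5, 5, 0), 2, 2,
                        dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(entropy_rate(det), 0)

  # worked example: pi = (2/3, 1/3), P = [[.5,.5],[1,0]], 2 states
  tm <- make_tm(matrix(c(1, 1, 2, 0), 2, 2, byrow = TRUE,
                       dimnames = list(c("a", "b"), c("a", "b"))),
                pi = c(2 / 3, 1 / 3))
  expect_equal(entropy_rate(tm), 2 / 3, tolerance = 1e-9)

  # uniform transitions over N states with uniform occupancy: maximal
  N <- 4
  u <- make_tm(matrix(1, N, N, dimnames = list(letters[1:N], letters[1:N])),
               pi = rep(1 / N, N))
  expect_equal(entropy_rate(u), 1, tolerance = 1e-12)

  single <- make_tm(matrix(2, 1, 1, dimnames = list("a", "a")), pi = 1)
  expect_error(entropy_rate(single), "single-state")
})

test_that("entropy rate is invariant to relabeling and duplication", {
  tab <- make_label_table(list(f1 = c("a", "b", "b", "a", "c")),
                          list(f1 = c(0.05, 0.05, 0.3, 0.05)))
  er1 <- entropy_rate(make_transition_matrix(tab))
  swapped <- tab
  swapped$label <- chartr("abc", "bca", tab$label)
  expect_equal(entropy_rate(make_transition_matrix(swapped)), er1)
  # concatenating the data with itself (as a second file) leaves probs alone
  dup <- tab
  dup$file <- "f2"
  both <- segment_table(c(tab$file, dup$file), c(tab$onset, dup$onset),
                        c(tab$offset, dup$offset), c(tab$label, dup$label))
  tm1 <- make_transition_matrix(tab); tm2 <- make_transition_matrix(both)
  expect_equal(tm2$counts, tm1$counts * 2)
  expect_equal(tm2$probs, tm1$probs)
  expect_equal(entropy_rate(tm2), er1)
})

test_that("repetition bouts follow the worked example and CV conventions", {
  bouts <- structure(list(bouts = list(strsplit("abcaaabc", "")[[1]]),
                          meta = data.frame(file = "f", onset = 0)),
                     class = "bout_set")
  r <- repetition_stats(bouts)
  a <- r[r$label == "a", ]
  expect_equal(a$n_bouts, 2L)
  expect_equal(a$max_len, 3L)
  expect_equal(a$mean_len, 2)
  expect_equal(a$cv_len, 0.5)     # population s.d. 1 / mean 2

  aaa <- structure(list(bouts = list(c("a", "a", "a")),
                        meta = data.frame(file = "f", onset = 0)),
                   class = "bout_set")
  r3 <- repetition_stats(aaa)
  expect_equal(r3$n_bouts, 1L)
  expect_equal(r3$mean_len, 3)
  expect_equal(r3$cv_len, 0)
})

test_that("introductory notes require silence adjacency and a dominant transition", {
  # classic grammar: bouts of i,i,i,a,b,c separated by long silences
  # two bouts per file, separated by > 200 ms so silence becomes a state
  seqs <- list(); gaps <- list()
  for (k in 1:6) {
    b1 <- c(rep("i", 1 + k %% 3), "a", "b", "c")
    b2 <- c(rep("i", 1 + (k + 1) %% 3), "a", "b", "c")
    seqs[[paste0("f", k)]] <- c(b1, b2)
    gaps[[paste0("f", k)]] <- c(rep(0.05, length(b1) - 1), 0.4,
                                rep(0.05, length(b2) - 1))
  }
  tab <- make_label_table(seqs, gaps)
  tm <- make_transition_matrix(tab)
  expect_identical(find_intro_notes(tm), "i")

  # no silence-adjacent repeats: empty set possible
  tabn <- make_label_table(list(f1 = c("a", "b", "a", "b")),
                           list(f1 = rep(0.05, 3)))
  expect_length(find_intro_notes(make_transition_matrix(tabn)), 0L)

  # two intro types with near-equal silence exit probabilities: both kept
  seqs2 <- list(f1 = c("i", "a", "b", "j", "a", "b"),
                f2 = c("j", "a", "b", "i", "a", "b"))
  gaps2 <- lapply(seqs2, function(s) c(0.05, 0.05, 0.4, 0.05, 0.05))
  tm2 <- make_transition_matrix(make_label_table(seqs2, gaps2))
  expect_setequal(find_intro_notes(tm2), c("i", "j"))
})

test_that("call detection uses the one-third isolated-utterance rule", {
  # token c produced alone in 2 of 5 utterances (2/5 > 1/3): call
  seqs <- list(f1 = c("c"), f2 = c("c"),
               f3 = c("a", "c", "b"), f4 = c("a", "c", "b"),
               f5 = c("a", "c", "b"))
  gaps <- list(f1 = numeric(), f3 = c(0.05, 0.05), f4 = c(0.05, 0.05),
               f5 = c(0.05, 0.05), f2 = numeric())
  tab <- make_label_table(seqs, gaps)
  calls <- find_calls(tab, intro = character())
  expect_true("c" %in% calls)
  expect_false("a" %in% calls)   # always mid-motif
  # token always alone
  alone <- make_label_table(list(f1 = "k", f2 = "k", f3 = "k"),
                            list(f1 = numeric(), f2 = numeric(),
                                 f3 = numeric()))
  expect_identical(find_calls(alone), "k")
})

test_that("syntax features select the most-repeated song syllable", {
  # grammar where only the intro note repeats: selected type is a motif
  # syllable with mean length ~1
  seqs <- list(); gaps <- list()
  for (k in 1:6) {
    b1 <- c(rep("i", 2 + k %% 2), "a", "b", "c", "a", "b", "c")
    b2 <- c(rep("i", 2 + (k + 1) %% 2), "a", "b", "c", "a", "b", "c")
    seqs[[paste0("f", k)]] <- c(b1, b2)
    gaps[[paste0("f", k)]] <- c(rep(0.05, length(b1) - 1), 0.4,
                                rep(0.05, length(b2) - 1))
  }
  sf <- syntax_features(make_label_table(seqs, gaps))
  expect_true(sf$rep_type %in% c("a", "b", "c"))
  expect_equal(sf$mean_rep_bout_len, 1)
  expect_true("i" %in% sf$intro_notes)
  expect_true(sf$entropy_rate_norm >= 0 && sf$entropy_rate_norm <= 1)

  # single-type repertoire: repetition feature missing
  lone <- make_label_table(list(f1 = c("a", "a", "a")),
                           list(f1 = c(0.05, 0.05)))
  sf1 <- syntax_features(lone)
  expect_true(is.na(sf1$mean_rep_bout_len) || sf1$rep_type == "a")
})

test_that("stereotyped adult grammar yields low normalized entropy rate", {
  arch <- synth_preset("adult")$archetypes
  spec <- synth_spec(song_grammar(c("a", "b", "c"), intro = "i",
                                  intro_p = 1, epsilon = 0),
                     arch, n_files = 5, bouts_per_file = 3, seed = 11)
  out <- render_song(spec)
  sf <- syntax_features(out$truth)
  expect_lt(sf$entropy_rate_norm, 0.2)

  # and the fully deterministic single-pass grammar is (near) zero
  spec0 <- synth_spec(song_grammar(c("a", "b", "c"), intro = NULL,
                                   epsilon = 0, passes = 1),
                      arch[c("a", "b", "c")], n_files = 4,
                      bouts_per_file = 4, seed = 11)
  out0 <- render_song(spec0)
  tm0 <- make_transition_matrix(out0$truth)
  expect_lt(entropy_rate(tm0), 0.05)
})
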