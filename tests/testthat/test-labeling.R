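test_that("syllable spectrogram preparation standardizes dimensions", {
  rate <- 32000
  t <- seq(0, 0.06, by = 1 / rate)
  x <- c(numeric(3200), sin(2 * pi * 2000 * t), numeric(3200),
         sin(2 * pi * 3000 * t), numeric(3200))
  rec <- song_rec(x, rate, "f1")
  segs <- segment_table(rep("f1", 2),
                        c(0.1, 0.1 + length(t) / rate + 0.1),
                        c(0.1 + length(t) / rate,
                          0.1 + 2 * length(t) / rate + 0.1))
  sp <- prepare_syllable_spectrograms(rec, segs)
  # equal-duration syllables: identical vector lengths by construction
  expect_equal(nrow(sp$vectors), 2L)
  expect_equal(ncol(sp$vectors), sp$n_freq * sp$n_time)

  # over-long segments are represented at the clip duration
  long_rec <- song_rec(stats::rnorm(rate * 1.5) * 0.2, rate, "f1")
  long_segs <- segment_table("f1", 0.1, 1.2)
  spl <- prepare_syllable_spectrograms(long_rec, long_segs, max_dur = 0.870)
  expect_lte(spl$n_time * 128 / rate, 0.880)

  # an all-silence segment yields a finite floor vector
  sil <- song_rec(numeric(rate), rate, "f1")
  sps <- prepare_syllable_spectrograms(sil, segment_table("f1", 0.2, 0.3))
  expect_true(all(is.finite(sps$vectors)))

  # out-of-bounds segment errors with the row number
  expect_error(prepare_syllable_spectrograms(rec, segment_table("f1", 0.1, 60)),
               "row 1")
})

test_that("embedding is deterministic, co-locates duplicates and separates archetypes", {
  lb <- fx_labeling()
  sub_idx <- seq_len(min(80, nrow(lb$specs$vectors)))
  specs <- lb$specs
  specs$vectors <- specs$vectors[sub_idx, ]
  specs$segments <- specs$segments[sub_idx, ]

  e1 <- embed_umap(specs, seed = 11)
  e2 <- embed_umap(specs, seed = 11)
  expect_identical(e1, e2)

  # duplicated points land together
  dup <- specs
  dup$vectors <- rbind(specs$vectors, specs$vectors[1:5, ])
  ed <- embed_umap(dup, seed = 3)
  n <- nrow(specs$vectors)
  spread <- sqrt(max(rowSums((ed[n + 1:5, ] - ed[1:5, ])^2)))
  scale <- mean(sqrt(rowSums(sweep(ed, 2, colMeans(ed))^2)))
  expect_lt(spread, 0.25 * scale)

  # archetype separation: between-type centroid distance > within-type spread
  emb <- embed_umap(lb$specs, seed = 42)
  labs <- lb$truth$label
  cents <- do.call(rbind, lapply(unique(labs), function(l) {
    colMeans(emb[labs == l, , drop = FALSE])
  }))
  within <- mean(vapply(unique(labs), function(l) {
    sub <- emb[labs == l, , drop = FALSE]
    mean(sqrt(rowSums(sweep(sub, 2, colMeans(sub))^2)))
  }, numeric(1)))
  dc <- stats::dist(cents)
  expect_gt(min(dc), within)

  few <- specs
  few$vectors <- few$vectors[1:5, ]
  expect_error(embed_umap(few), "at least 10")
})

test_that("density clustering finds blobs, flags sparse scatter as noise", {
  set.seed(99)
  b1 <- cbind(stats::rnorm(200), stats::rnorm(200))
  b2 <- cbind(stats::rnorm(200) + 12, stats::rnorm(200))
  l2 <- cluster_hdbscan(rbind(b1, b2))
  expect_identical(attr(l2, "n_clusters"), 2L)

  l1 <- cluster_hdbscan(b1)
  expect_identical(attr(l1, "n_clusters"), 1L)

  set.seed(1)
  u <- cbind(stats::runif(400, 0, 400), stats::runif(400, 0, 400))
  lu <- cluster_hdbscan(u, min_cluster_size = 25)
  expect_gt(mean(lu == "noise"), 0.5)
})

test_that("label alignment assigns reserved categories to unmatched syllables", {
  ref <- segment_table(rep("f", 3), c(0.1, 0.5, 1.0), c(0.2, 0.6, 1.1),
                       c("a", "b", "a"))
  pred_same <- ref
  al <- align_labels(ref, pred_same)
  expect_equal(nrow(al), 3L)
  expect_equal(al$ref_label, al$cluster)

  # one extra predicted syllable: paired with reference category "x"
  pred_extra <- segment_table(rep("f", 4), c(0.1, 0.5, 1.0, 2.0),
                              c(0.2, 0.6, 1.1, 2.1), c("0", "1", "0", "9"))
  ax <- align_labels(ref, pred_extra)
  expect_equal(sum(ax$ref_label == "x"), 1L)
  expect_equal(ax$cluster[ax$ref_label == "x"], "9")

  # one missed syllable: paired with cluster "1000"
  pred_miss <- segment_table(rep("f", 2), c(0.1, 0.5), c(0.2, 0.6),
                             c("0", "1"))
  am <- align_labels(ref, pred_miss)
  expect_equal(sum(am$cluster == "1000"), 1L)
})

test_that("clustering scores match the direct entropy computation", {
  perfect <- matrix(c(5, 0, 0, 5), 2, 2)
  ev <- cluster_eval(perfect)
  expect_equal(c(ev$homogeneity, ev$completeness, ev$v_measure), c(1, 1, 1))

  one_cluster <- matrix(c(5, 5), 1, 2)
  ev2 <- cluster_eval(one_cluster)
  expect_equal(ev2$homogeneity, 0)
  expect_equal(ev2$completeness, 1)
  expect_equal(ev2$v_measure, 0)

  mixed <- matrix(c(4, 1, 1, 4), 2, 2)
  ev3 <- cluster_eval(mixed)
  oracle <- entropy_scores_oracle(mixed)
  expect_equal(ev3$homogeneity, oracle$homogeneity)
  expect_equal(ev3$v_measure, oracle$v_measure)
  expect_equal(ev3$v_measure, 0.278, tolerance = 1e-3)

  # random confusion matrices agree with the oracle
  set.seed(7)
  for (i in 1:25) {
    conf <- matrix(stats::rpois(12, 3), 3, 4)
    if (sum(conf) == 0) next
    ev <- cluster_eval(conf)
    or <- entropy_scores_oracle(conf)
    expect_equal(ev$homogeneity, or$homogeneity, tolerance = 1e-12)
    expect_equal(ev$completeness, or$completeness, tolerance = 1e-12)
    expect_equal(ev$v_measure, or$v_measure, tolerance = 1e-12)
    # role swap exchanges homogeneity and completeness
    sw <- cluster_eval(t(conf))
    expect_equal(sw$homogeneity, ev$completeness, tolerance = 1e-12)
    expect_equal(sw$completeness, ev$homogeneity, tolerance = 1e-12)
    # cluster renaming leaves scores alone
    perm <- cluster_eval(conf[sample(nrow(conf)), ])
    expect_equal(perm$v_measure, ev$v_measure, tolerance = 1e-12)
  }
})

test_that("label stability across embedding seeds is high on clean data", {
  lb <- fx_labeling()
  st <- stability_over_seeds(lb$specs, seeds = c(2, 9, 17),
                             ref_labels = lb$truth$label)
  expect_equal(nrow(st$per_seed), 3L)
  expect_lt(st$sd_v, 0.05)
  expect_true(all(st$per_seed$v_measure > 0.85))

  same <- stability_over_seeds(lb$specs, seeds = c(4, 4),
                               ref_labels = lb$truth$label)
  expect_equal(same$sd_v, 0)
})
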