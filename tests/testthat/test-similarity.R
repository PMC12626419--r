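test_that("similarity spectrograms are clipped/padded to 180 ms in the 2-6 kHz band", {
  rate <- 32000
  long <- song_rec(sin(2 * pi * 3000 * seq(0, 0.4, by = 1 / rate)), rate, "f")
  segs <- segment_table(c("f", "f"), c(0.02, 0.30), c(0.27, 0.35),
                        c("a", "b"))   # 250 ms and 50 ms syllables
  sp <- prep_similarity_spectrograms(long, segs)
  # both rows equal length: 180 ms worth of frames
  expect_equal(sp$n_time, length(seq(0, 0.18 * rate, by = 128)))
  # frequency rows limited to the 2-6 kHz band
  expect_lte(sp$n_freq, sum((0:(512 / 2)) * rate / 512 >= 2000 &
                            (0:(512 / 2)) * rate / 512 <= 6000))

  # per-syllable amplitude normalization: doubling the audio changes nothing
  louder <- song_rec(2 * long$samples, rate, "f")
  sp2 <- prep_similarity_spectrograms(louder, segs)
  expect_equal(sp2$vectors, sp$vectors, tolerance = 1e-9)
})

test_that("triplet loss and hardness classification follow their definitions", {
  expect_equal(triplet_loss(0, 0.1, 0.1), 0)
  expect_equal(triplet_loss(0.5, 0.3, 0.1), 0.3)
  expect_equal(triplet_loss(0.4, 0.4, 0), 0)
  expect_equal(triplet_loss(0.5, 0.3, 0.1, squared = TRUE),
               0.5^2 - 0.3^2 + 0.1)

  expect_equal(classify_triplet(0.5, 0.3, 0.1), "hard")
  expect_equal(classify_triplet(0.40, 0.45, 0.1), "semi_hard")
  expect_equal(classify_triplet(0.1, 0.9, 0.1), "zero")
  expect_equal(classify_triplet(c(0.5, 0.4, 0.1), c(0.3, 0.45, 0.9), 0.1),
               c("hard", "semi_hard", "zero"))
})

test_that("exact EMD satisfies closed forms, the 1-D oracle and metric axioms", {
  # identical sets
  set.seed(5)
  a <- matrix(stats::rnorm(40), 5)
  expect_equal(emd(a, a), 0, tolerance = 1e-7)

  # orthogonal unit point masses in 8-D: sqrt(2), the hypersphere maximum
  e1 <- matrix(c(1, rep(0, 7)), 1)
  e2 <- matrix(c(0, 1, rep(0, 6)), 1)
  expect_equal(emd(e1, e2), sqrt(2), tolerance = 1e-12)
  expect_equal(round(emd(e1, e2), 2), 1.41)

  # point masses at distance d transport at cost d
  p <- matrix(rep(0.3, 8), 1); q <- matrix(rep(0.3, 8) + 0.25, 1)
  expect_equal(emd(p, q), sqrt(sum((p - q)^2)), tolerance = 1e-12)

  # 1-D closed form, including unequal sizes
  set.seed(11)
  for (i in 1:10) {
    x <- matrix(stats::runif(sample(3:40, 1)))
    y <- matrix(stats::runif(sample(3:40, 1)))
    expect_equal(emd(x, y), emd_1d_oracle(x, y), tolerance = 1e-10)
  }

  # symmetry, non-negativity, triangle inequality on point clouds
  set.seed(21)
  for (i in 1:5) {
    A <- matrix(stats::rnorm(24), 3); B <- matrix(stats::rnorm(24), 3)
    C <- matrix(stats::rnorm(24), 3)
    dab <- emd(A, B); dba <- emd(B, A)
    expect_equal(dab, dba, tolerance = 1e-10)
    expect_gte(dab, 0)
    expect_lte(dab, emd(A, C) + emd(C, B) + 1e-10)
  }
})

test_that("MMD matches kernel closed forms and grows with separation", {
  set.seed(5)
  a <- matrix(stats::rnorm(80), 10)
  expect_equal(mmd(a, a, sigma = 1), 0, tolerance = 1e-12)

  # two point masses at distance sigma: sqrt(2 - 2 exp(-1/2))
  p <- matrix(0, 1, 8); q <- matrix(c(2, rep(0, 7)), 1)
  expect_equal(mmd(p, q, sigma = 2), sqrt(2 - 2 * exp(-0.5)), tolerance = 1e-12)
  # far-apart masses approach sqrt(2)
  far <- matrix(c(1e4, rep(0, 7)), 1)
  expect_equal(mmd(p, far, sigma = 1), sqrt(2), tolerance = 1e-9)

  # monotone non-decreasing in separation for translated Gaussian clouds
  set.seed(31)
  base <- matrix(stats::rnorm(400), 50)
  prev <- -Inf
  for (shift in c(0, 0.5, 1, 2, 4)) {
    b <- base + matrix(rep(c(shift, rep(0, 7)), each = 50), 50)
    m <- mmd(base, b, sigma = 1)
    expect_gte(m, prev - 1e-9)
    prev <- m
  }

  expect_error(mmd(p, q, bandwidth_ref = matrix(0, 5, 8)), "degenerate")
})

test_that("the embedder architecture produces unit-norm 8-D embeddings", {
  model <- build_embedder(c(24, 16), preset = "desk", seed = 1)
  x1 <- matrix(stats::rnorm(24 * 16), 1)
  e1 <- embed_syllables(model, x1)
  expect_equal(dim(e1), c(1L, 8L))
  expect_equal(sum(e1^2), 1, tolerance = 1e-9)

  xk <- matrix(stats::rnorm(5 * 24 * 16), 5)
  ek <- embed_syllables(model, xk)
  expect_equal(dim(ek), c(5L, 8L))
  expect_equal(rowSums(ek^2), rep(1, 5), tolerance = 1e-9)

  # the full-scale architecture builds and runs a forward pass
  full <- build_embedder(c(64, 40), preset = "full", seed = 1)
  ef <- embed_syllables(full, matrix(stats::rnorm(64 * 40), 1))
  expect_equal(dim(ef), c(1L, 8L))
  expect_equal(sum(ef^2), 1, tolerance = 1e-9)

  expect_error(build_embedder(c(4, 4)), "input_shape")
})

test_that("training separates types, follows the margin schedule, and is seeded", {
  o1 <- render_song(synth_preset("adult", n_files = 5, bouts_per_file = 3,
                                 seed = 21))
  o2 <- render_song(synth_preset("adult", n_files = 5, bouts_per_file = 3,
                                 seed = 22))
  tr1 <- o1$truth[o1$truth$label != "noise", ]
  tr2 <- o2$truth[o2$truth$label != "noise", ]
  class(tr1) <- class(tr2) <- c("segment_table", "data.frame")
  s1 <- prep_similarity_spectrograms(o1$recs, tr1, downsample = c(24, 16))
  s2 <- prep_similarity_spectrograms(o2$recs, tr2, downsample = c(24, 16))
  X <- rbind(s1$vectors, s2$vectors)
  labels <- c(tr1$label, tr2$label)
  birds <- rep(c("b1", "b2"), c(nrow(tr1), nrow(tr2)))

  fit <- train_embedder(X, labels, birds, input_shape = c(24, 16),
                        epochs = 12, seed = 5)
  expect_true(all(fit$history$margin %in% c(0.1, 0.3, 0.5, 0.7)))
  expect_true(all(diff(fit$history$margin) >= 0))

  E <- embed_syllables(fit$model, X)
  D <- as.matrix(stats::dist(E))
  same <- outer(labels, labels, "==") & upper.tri(D)
  diff_ <- !outer(labels, labels, "==") & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[diff_]))

  fit2 <- train_embedder(X, labels, birds, input_shape = c(24, 16),
                         epochs = 12, seed = 5)
  expect_equal(tail(fit$history$loss, 1), tail(fit2$history$loss, 1),
               tolerance = 1e-9)

  expect_error(train_embedder(X, labels, rep("b1", length(birds)),
                              input_shape = c(24, 16)),
               "2 birds")
})

test_that("comparison protocols sample pools as documented", {
  set.seed(8)
  pool <- matrix(stats::rnorm(500 * 8), 500)
  pool <- pool / sqrt(rowSums(pool^2))
  self <- compare_birds(pool, kind = "self", seed = 3)
  expect_equal(self$kind, "self")
  expect_equal(self$n_a, 250L)
  expect_equal(self$n_b, 250L)
  expect_gte(self$emd, 0)
  expect_equal(self$seed, 3L)

  # above the split limit: two fixed-size samples
  big <- matrix(stats::rnorm(450 * 8), 450)
  s2 <- compare_birds(big, kind = "self", seed = 3, split_limit = 400,
                      sample_n = 150)
  expect_equal(c(s2$n_a, s2$n_b), c(150L, 150L))

  # cross comparisons cap each side
  other <- matrix(stats::rnorm(600 * 8), 600)
  cr <- compare_birds(pool, other, kind = "unrelated", seed = 1,
                      cross_max = 200)
  expect_equal(c(cr$n_a, cr$n_b), c(200L, 200L))

  # identical pools under one seed are identical samples
  tut <- compare_birds(pool, pool, kind = "tutor", seed = 2, cross_max = 300)
  expect_equal(tut$emd, 0, tolerance = 1e-7)
})

test_that("contrast indices follow the absolute-ratio definition", {
  expect_equal(contrast_index(0, 0.5), 1)
  expect_equal(contrast_index(0.4, 0.4), 0)
  expect_equal(contrast_index(0.2, 0.6), 0.5)
  expect_equal(tutor_contrast_index(0.2, 0.6), 0.5)
  expect_error(contrast_index(0, 0), "denominator")
  expect_error(tutor_contrast_index(0, 0), "denominator")
})
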