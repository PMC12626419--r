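test_that("amplitude segmentation follows the crossing rules on a hand-built trace", {
  # trace at 0-based frames; hop 512 @ 32 kHz -> frame_t = 16 ms
  rate <- 32000
  mk_trace <- function(r) {
    structure(list(rmse = r, times = (seq_along(r) - 1L) * 512 / rate,
                   hop = 512, frame_len = 2048, rate = rate,
                   n_samples = length(r) * 512L, source_id = "t",
                   fine_rmse = NULL, fine_hop = NULL, fine_frame = NULL),
              class = "amp_trace")
  }
  # two bursts separated by ~64 ms (< 300 ms): onset-to-onset rule applies
  r <- c(rep(0, 5), rep(1, 4), rep(0, 4), rep(1, 4), rep(0, 8))
  st <- segment_amplitude(mk_trace(r), onset_thr = 0.5, offset_thr = 0.3,
                          refine = FALSE)
  frame_t <- 512 / rate
  expect_equal(nrow(st), 2L)
  # onsets at the derivative crossings (hand-walked): frames 5 and 13
  expect_equal(st$onset, c(5, 13) * frame_t, tolerance = 1e-9)
  # gap < 300 ms: first offset equals second onset
  expect_equal(st$offset[1], st$onset[2])
  # last offset at the downward RMSE crossing (frame 17)
  expect_equal(st$offset[2], 17 * frame_t, tolerance = 1e-9)

  # flat trace below threshold: nothing detected
  expect_equal(nrow(segment_amplitude(mk_trace(rep(0.01, 30)), 0.5, 0.3)), 0L)

  # single burst: offset from the offset-threshold crossing
  r1 <- c(rep(0, 5), rep(1, 6), rep(0, 10))
  s1 <- segment_amplitude(mk_trace(r1), 0.5, 0.3, refine = FALSE)
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$onset, 5 * frame_t, tolerance = 1e-9)
  expect_equal(s1$offset, 11 * frame_t, tolerance = 1e-9)
})

test_that("bursts separated by more than 300 ms end at the offset crossing", {
  rate <- 32000
  frame_t <- 512 / rate
  r <- c(rep(0, 4), rep(1, 4), rep(0, 25), rep(1, 4), rep(0, 6))
  tr <- structure(list(rmse = r, times = (seq_along(r) - 1L) * frame_t,
                       hop = 512, frame_len = 2048, rate = rate,
                       n_samples = length(r) * 512L, source_id = "t",
                       fine_rmse = NULL),
                  class = "amp_trace")
  st <- segment_amplitude(tr, 0.5, 0.3, refine = FALSE)
  expect_equal(nrow(st), 2L)
  expect_lt(st$offset[1], st$onset[2])         # not onset-to-onset
  expect_equal(st$offset[1], 8 * frame_t, tolerance = 1e-9)
})

test_that("event matching agrees with the brute-force assignment oracle", {
  m <- match_events(c(0.1, 0.5, 1.0), c(0.105, 0.52, 0.995, 1.4), 0.01)
  expect_equal(m$tp, 2L)
  expect_equal(m$fp, 2L)
  expect_equal(m$fn, 1L)

  m2 <- match_events(1:5 / 10, 1:5 / 10, 0.01)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(5L, 0L, 0L))

  m3 <- match_events(1:4 / 10, 1:4 / 10 + 0.02, 0.01)
  expect_equal(m3$tp, 0L)

  set.seed(42)
  for (i in 1:30) {
    ref <- sort(stats::runif(sample(0:8, 1)))
    pred <- sort(stats::runif(sample(0:8, 1)))
    tol <- stats::runif(1, 0.02, 0.3)
    m <- match_events(ref, pred, tol)
    expect_identical(m$tp, brute_force_match(ref, pred, tol))
    expect_true(all(abs(m$pairs$delta) <= tol))
    # count-structure symmetry: swapping ref/pred swaps fp and fn
    ms <- match_events(pred, ref, tol)
    expect_identical(c(ms$tp, ms$fp, ms$fn), c(m$tp, m$fn, m$fp))
  }
})

test_that("F1 follows the printed formula with 0/0 defined as 0", {
  f <- seg_f1(list(tp = 2, fp = 2, fn = 1))
  expect_equal(f$precision, 0.5)
  expect_equal(f$recall, 2 / 3, tolerance = 1e-4)
  expect_equal(f$f1, 0.5714, tolerance = 1e-4)
  expect_equal(seg_f1(list(tp = 7, fp = 0, fn = 0))[c("precision", "recall", "f1")],
               list(precision = 1, recall = 1, f1 = 1))
  expect_equal(seg_f1(list(tp = 0, fp = 0, fn = 0))$f1, 0)
  # harmonic-mean identity whenever P + R > 0
  set.seed(1)
  for (i in 1:20) {
    f <- seg_f1(list(tp = sample(0:20, 1), fp = sample(0:20, 1),
                     fn = sample(0:20, 1)))
    if (f$precision + f$recall > 0) {
      expect_equal(f$f1, 2 * f$precision * f$recall / (f$precision + f$recall),
                   tolerance = 1e-12)
    }
  }
})

test_that("time deltas are signed pred - ref with a median-absolute summary", {
  m <- match_events(1:5 / 10, 1:5 / 10, 0.01)
  expect_true(all(time_deltas(m)$deltas == 0))
  m2 <- match_events(1:5 / 10, 1:5 / 10 + 0.003, 0.01)
  expect_equal(time_deltas(m2)$median_abs, 0.003, tolerance = 1e-9)
  expect_true(all(time_deltas(m2)$deltas > 0))
})

test_that("segment tables round-trip through CSV and validate rows", {
  tab <- segment_table(c("f1", "f1", "f2"), c(0.1, 0.5, 0.2),
                       c(0.2, 0.9, 0.35), c("a", "b", ""))
  path <- withr::local_tempfile(fileext = ".csv")
  write_segment_table(tab, path)
  back <- read_segment_table(path)
  expect_equal(back$onset, tab$onset, tolerance = 1e-6)
  expect_equal(back$offset, tab$offset, tolerance = 1e-6)
  expect_equal(back$label, tab$label)
  expect_equal(back$file, tab$file)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("onset,offset,label,file", "0.5,0.4,a,f1"), bad)
  expect_error(read_segment_table(bad), "row")

  nolab <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("onset,offset,file", "0.1,0.2,f1"), nolab)
  tb <- read_segment_table(nolab)
  expect_equal(tb$label, "")
})

test_that("threshold optimization maximizes mean onset-F1 with the tie rule", {
  a <- fx_adult()
  traces <- list(bird1 = a$traces[1:2], bird2 = a$traces[3:4])
  files12 <- names(a$recs)[1:2]
  refs <- list(bird1 = a$truth[a$truth$file %in% files12, ],
               bird2 = a$truth[!a$truth$file %in% files12, ])
  grid <- expand.grid(onset_thr = c(0.04, 0.45), offset_thr = 0.05)
  opt <- optimize_thresholds(traces, refs, grid)
  # exhaustive oracle over the same grid
  f1_of <- function(g) {
    mean(vapply(names(traces), function(b) {
      pred <- do.call(rbind, lapply(traces[[b]], segment_amplitude,
                                    onset_thr = grid$onset_thr[g],
                                    offset_thr = grid$offset_thr[g]))
      seg_metrics(refs[[b]], pred)$onset$f1
    }, numeric(1)))
  }
  oracle <- vapply(seq_len(nrow(grid)), f1_of, numeric(1))
  expect_equal(opt$mean_f1, max(oracle))
  expect_equal(opt$onset_thr, grid$onset_thr[which.max(oracle)])

  single <- optimize_thresholds(traces, refs,
                                data.frame(onset_thr = 0.04, offset_thr = 0.05))
  expect_equal(single$onset_thr, 0.04)

  # equal scores tie-break to the lower onset threshold
  tie <- optimize_thresholds(traces, refs,
                             data.frame(onset_thr = c(0.9, 0.8),
                                        offset_thr = c(0.5, 0.5)))
  expect_equal(tie$onset_thr, 0.8)

  expect_error(optimize_thresholds(traces, refs, data.frame()), "grid")
})

test_that("clean synthetic onsets are recovered within one RMSE hop", {
  a <- fx_adult()
  hop_s <- 512 / a$recs[[1]]$rate
  for (f in names(a$recs)) {
    ref <- a$truth$onset[a$truth$file == f & a$truth$label != "noise"]
    pred <- a$pred$onset[a$pred$file == f]
    m <- match_events(ref, pred, hop_s)
    expect_identical(m$fn, 0L)
  }
})
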