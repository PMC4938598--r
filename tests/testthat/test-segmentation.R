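test_that("noise sd estimator has the stated closed forms and consistency", {
  expect_equal(estimate_noise_sd(rep(1.5, 50)), 1e-8)  # epsilon floor
  cc <- 0.4
  x <- rep(c(0, cc), 25)
  expect_equal(estimate_noise_sd(x), cc / (0.6745 * sqrt(2)))
  withr::local_seed(2)
  draws <- rnorm(10000, sd = 0.2)
  expect_lt(abs(estimate_noise_sd(draws) - 0.2) / 0.2, 0.05)
  expect_error(estimate_noise_sd(1), "at least 2")
})

test_that("outlier smoothing shrinks lone spikes and keeps genuine levels", {
  p <- segmentation_params()
  sd0 <- 0.1
  x <- rep(0, 21); x[11] <- 10 * sd0
  sm <- smooth_outliers(x, p, noise_sd = sd0)
  expect_equal(sm[11], 2 * sd0)  # nearest neighbor 0, shrunk toward original
  expect_equal(sm[-11], x[-11])
  # clean data is untouched
  withr::local_seed(8)
  y <- rnorm(100, sd = 0.1)
  expect_identical(smooth_outliers(y, p, noise_sd = 0.1), y)
  # hand-traced 12-marker vector: two adjacent equal spikes form a genuine
  # level; each has a zero-distance neighbor and is retained
  z <- c(rep(0, 5), 1, 1, rep(0, 5))
  expect_identical(smooth_outliers(z, p, noise_sd = 0.1), z)
  # ... but a lone spike of the same height is shrunk
  z2 <- c(rep(0, 5), 1, rep(0, 6))
  expect_equal(smooth_outliers(z2, p, noise_sd = 0.1)[6], 0.2)
})

test_that("max arc statistic matches the exhaustive double-loop oracle", {
  expect_equal(max_arc_statistic(rep(2, 12), 4)$stat, 0)  # no variation
  # symmetric step: the maximizer is one of the two level blocks
  r <- max_arc_statistic(c(rep(0, 4), rep(1, 4)), 4)
  expect_true(identical(c(r$arc_start, r$arc_end), c(1L, 4L)) ||
              identical(c(r$arc_start, r$arc_end), c(5L, 8L)))
  withr::local_seed(31)
  for (n in c(8, 12, 17, 23, 30)) {
    for (rep_i in 1:3) {
      x <- rnorm(n) + c(rep(0, n %/% 2), rep(runif(1, 0, 2), n - n %/% 2))
      got <- max_arc_statistic(x, 4)
      want <- oracle_max_arc(x, 4)
      expect_equal(got$stat, want$stat, tolerance = 1e-10)
      expect_equal(c(got$arc_start, got$arc_end), c(want$i, want$j))
    }
  }
  expect_false(max_arc_statistic(rnorm(6), 4)$tested)  # no-test signal
})

test_that("permutation p-values match full enumeration on tiny stretches", {
  p <- segmentation_params(n_perm = 1000, min_width = 2)
  # constant vector: every ordering reproduces T_obs, p = 1
  pv <- permutation_pvalue(rep(1, 5), max_arc_statistic(rep(1, 5), 2)$stat, p)
  expect_true(pv$exact)
  expect_equal(pv$p, 1)
  withr::local_seed(13)
  for (rep_i in 1:3) {
    x <- rnorm(6)
    t_obs <- max_arc_statistic(x, 2)$stat
    pv <- permutation_pvalue(x, t_obs, p)
    expect_true(pv$exact)
    expect_equal(pv$p, oracle_perm_pvalue(x, t_obs, 2))
  }
})

test_that("a strong step is significant at alpha with 1000 permutations", {
  p <- segmentation_params(n_perm = 1000)
  x <- c(rnorm(20, 0, 0.1), rnorm(20, 10 * 0.1, 0.1))
  t_obs <- max_arc_statistic(x, p$min_width)$stat
  pv <- withr::with_seed(1, permutation_pvalue(x, t_obs, p))
  expect_false(pv$exact)
  expect_lte(pv$p, 0.001)
})

test_that("segmentation recovers planted boundaries", {
  p <- segmentation_params(n_perm = 1000)
  # constant chromosome: one segment covering everything
  segs <- segment_chromosome(rep(0.3, 100), 1:100 * 1000, p)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_markers, 100)
  expect_equal(segs$seg_mean, 0.3)
  # noise-free step at marker 20
  x <- c(rep(0, 20), rep(1, 20))
  segs <- segment_chromosome(x, 1:40 * 1000, p)
  expect_equal(segs$end_idx, c(20, 40))
  expect_equal(segs$seg_mean, c(0, 1))
  # 500 markers, 3 planted jumps of >= 4 sd, noise sd 0.15
  withr::local_seed(6)
  truth_levels <- c(rep(0, 125), rep(0.8, 125), rep(-0.2, 125), rep(0.7, 125))
  y <- truth_levels + rnorm(500, sd = 0.15)
  segs <- segment_chromosome(y, 1:500 * 1000, p)
  expect_equal(nrow(segs), 4)
  expect_true(all(abs(segs$end_idx[1:3] - c(125, 250, 375)) <= 1))
})

test_that("segments always tile the markers and respect min_width", {
  p <- segmentation_params(n_perm = 500)
  withr::local_seed(17)
  for (rep_i in 1:5) {
    n <- sample(30:200, 1)
    x <- rnorm(n, sd = 0.2) +
      rep(c(0, runif(1, 0, 1.5)), c(n %/% 3, n - n %/% 3))
    segs <- segment_chromosome(x, seq_len(n) * 500, p)
    expect_equal(sum(segs$n_markers), n)
    expect_equal(segs$start_idx, c(1L, head(segs$end_idx, -1) + 1L))
    expect_true(all(segs$n_markers >= p$min_width))
    # segment means are recomputable from the covered ratios
    for (k in seq_len(nrow(segs))) {
      expect_equal(segs$seg_mean[k], mean(x[segs$start_idx[k]:segs$end_idx[k]]))
    }
  }
})

test_that("sd-undo merges weak boundaries and guarantees the gap", {
  x <- c(rep(0, 10), rep(0.2, 10))
  segs <- segments_from_cuts(x, 1:20 * 100, 10L)
  expect_equal(nrow(sd_undo(segs, x, 0.5, noise_sd = 1)), 1)  # 0.2 < 0.5
  y <- c(rep(0, 10), rep(0.8, 10))
  segs2 <- segments_from_cuts(y, 1:20 * 100, 10L)
  expect_equal(nrow(sd_undo(segs2, y, 0.5, noise_sd = 1)), 2)  # 0.8 >= 0.5
  # chain 0 / 0.3 / 0.9: weakest first, then re-evaluate
  z <- c(rep(0, 10), rep(0.3, 10), rep(0.9, 10))
  segs3 <- segments_from_cuts(z, 1:30 * 100, c(10L, 20L))
  undone <- sd_undo(segs3, z, 0.5, noise_sd = 1)
  expect_equal(undone$seg_mean, c(0.15, 0.9))
  expect_equal(undone$end_idx, c(20, 30))
  # exhaustive oracle over all legal removal orders on <= 4 segments:
  # every order that repeatedly removes some below-threshold boundary must
  # land on the same final segmentation
  removal_oracle <- function(means, sizes, thr) {
    explore <- function(m, s) {
      gaps <- abs(diff(m))
      weak <- which(gaps < thr)
      if (length(weak) == 0) return(list(m))
      out <- list()
      for (k in weak) {
        mm <- m; ss <- s
        mm[k] <- (m[k] * s[k] + m[k + 1] * s[k + 1]) / (s[k] + s[k + 1])
        ss[k] <- s[k] + s[k + 1]
        out <- c(out, explore(mm[-(k + 1)], ss[-(k + 1)]))
      }
      out
    }
    unique(lapply(explore(means, sizes), function(v) round(v, 12)))
  }
  final <- removal_oracle(c(0, 0.3, 0.9), c(10, 10, 10), 0.5)
  expect_length(final, 1)
  expect_equal(undone$seg_mean, final[[1]])
  # gap guarantee on random segmentations
  withr::local_seed(23)
  for (rep_i in 1:5) {
    n <- 60
    w <- rnorm(n, sd = 0.3)
    cuts <- sort(sample(5:55, 3))
    s0 <- segments_from_cuts(w, seq_len(n) * 10, cuts)
    u <- sd_undo(s0, w, 0.5, noise_sd = 0.3)
    expect_lte(nrow(u), nrow(s0))
    if (nrow(u) > 1) expect_true(all(abs(diff(u$seg_mean)) >= 0.5 * 0.3))
  }
})

test_that("raising alpha never removes change-points on a fixed input", {
  withr::local_seed(41)
  x <- rnorm(150, sd = 0.2) +
    rep(c(0, 0.45, 0.1), c(50, 50, 50))
  counts <- vapply(c(0.001, 0.01, 0.05), function(a) {
    p <- segmentation_params(alpha = a, n_perm = 1000, undo_sd = 0, seed = 9)
    nrow(segment_chromosome(x, 1:150 * 1000, p))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
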