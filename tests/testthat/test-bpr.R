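two_segment_profile <- function(means, chrom = "1") {
  n <- length(means)
  out <- tibble::tibble(
    sample = "s1", chrom = chrom,
    start_idx = seq(1L, by = 10L, length.out = n),
    end_idx = seq(10L, by = 10L, length.out = n),
    start_pos = seq(1L, by = 10L, length.out = n) * 100,
    end_pos = seq(10L, by = 10L, length.out = n) * 100,
    n_markers = 10L, seg_mean = means)
  class(out) <- c("segmentation_profile", class(out))
  out
}

test_that("breakpoint detection applies the strict > 0.6 jump rule", {
  # difference exactly 0.6: no BPR
  expect_equal(nrow(detect_bprs(two_segment_profile(c(0, 0.6)))), 0)
  # 0.7 jump: the stretch between last-left and first-right probe
  prof <- two_segment_profile(c(0, 0.7))
  b <- detect_bprs(prof)
  expect_equal(nrow(b), 1)
  expect_equal(b$start_pos, prof$end_pos[1])
  expect_equal(b$end_pos, prof$start_pos[2])
  # losses count like gains
  expect_equal(nrow(detect_bprs(two_segment_profile(c(0.2, -0.5)))), 1)
})

test_that("only planted jumps above threshold yield BPRs in a clean sample", {
  spec <- cohort_spec(
    entities = c(A = 1), normal = c(normal = 1),
    chromosomes = tibble::tibble(chrom = "1", n_probes = 400L, spacing = 1000),
    bprs = tibble::tibble(chrom = "1", left_probe = c(50L, 150L, 250L),
                          len = 40L, jump = c(0.5, 1.0, 2.0),
                          A = 1, normal = 0),
    noise_sd = 0, seed = 2)
  sim <- simulate_cohort(spec)
  prof <- segment_profile(sim$signal,
                          segmentation_params(n_perm = 1000, seed = 2))
  b <- detect_bprs(prof[prof$sample == "A_001", ])
  # 0.5 jump is below the 0.6 cut; the 1.0 and 2.0 segments contribute
  # two boundaries each
  expect_equal(nrow(b), 4)
  expect_setequal(b$start_pos, c(150000, 190000, 250000, 290000))
})

test_that("aggregation counts carriers per group with exact interval identity", {
  bprs <- tibble::tibble(
    sample = c("a1", "a2", "a3", "b1"),
    chrom = "2",
    start_pos = c(100, 100, 100, 100),
    end_pos = c(200, 200, 200, 200))
  groups <- tibble::tibble(sample = c("a1", "a2", "a3", "b1", "n1"),
                           group = c("A", "A", "A", "B", "normal"))
  sizes <- c(A = 3L, B = 2L, normal = 1L)
  cat1 <- aggregate_catalog(bprs, groups, sizes)
  expect_equal(nrow(cat1), 1)
  expect_equal(cat1$count_A, 3L)
  expect_equal(cat1$count_B, 1L)
  expect_equal(cat1$cancer_total, 4L)
  # intervals differing by one probe stay distinct records
  bprs2 <- dplyr::bind_rows(bprs, tibble::tibble(
    sample = "a1", chrom = "2", start_pos = 100, end_pos = 201))
  expect_equal(nrow(aggregate_catalog(bprs2, groups, sizes)), 2)
  expect_error(aggregate_catalog(
    dplyr::mutate(bprs, sample = "zz"), groups, sizes), "without group")
})

test_that("published catalog identities hold: cancer totals and frequencies", {
  counts <- read_count_catalog()
  ent <- as.matrix(counts[, study_entities])
  expect_equal(unname(rowSums(ent)), counts$cancer)
  # worked examples: 30/377 -> 7.96, 170/1104 -> 15.40, 0 -> 0.00
  expect_equal(round_half_away(100 * 30 / 377, 2), 7.96)
  expect_equal(round_half_away(100 * 170 / 1104, 2), 15.4)
  expect_equal(round_half_away(100 * 0 / 377, 2), 0)
})

test_that("the four-class rule reproduces the published worked examples", {
  p <- bpr_params()
  # >=1% in 4 of 8 entities, normal 0: cancer-specific
  expect_equal(classify_bpr(c(12.47, 0, 1.47, 1.37, 0, 0, 0, 3.67), 0, p), 2L)
  # >=1% in 4 of 8 entities, normal 11.81: common
  expect_equal(classify_bpr(c(0.27, 16.40, 4.12, 0, 1.36, 0, 0, 25.69), 11.81, p), 3L)
  # one entity only: entity-specific, regardless of normal
  expect_equal(classify_bpr(c(0.53, 0.53, 0, 0, 15.40, 0, 0, 0), 0, p), 1L)
  expect_equal(classify_bpr(c(0.27, 0, 11.18, 0.69, 0, 0, 0, 0), 1.16, p), 1L)
  # nothing reaches 1%: no class
  expect_equal(classify_bpr(rep(0, 8), 0, p), 4L)
  # k >= 2 but below the entity fraction (needs > 8 entities)
  expect_warning(cl <- classify_bpr(c(2, 2, rep(0, 10)), 0, p), "no class")
  expect_equal(cl, 4L)
  # invariance under entity reordering
  f <- c(12.47, 0, 1.47, 1.37, 0, 0, 0, 3.67)
  withr::local_seed(4)
  for (i in 1:5) expect_equal(classify_bpr(sample(f), 0, p), 2L)
})

test_that("classification is total and uses unrounded frequencies", {
  p <- bpr_params()
  withr::local_seed(12)
  for (i in 1:50) {
    fr <- runif(8, 0, 30) * rbinom(8, 1, 0.5)
    cl <- suppressWarnings(classify_bpr(fr, runif(1, 0, 5), p))
    expect_true(cl %in% 1:4)
  }
  # knife-edge: 0.999999 vs 1.000001 percent
  expect_equal(classify_bpr(c(0.999999, rep(0, 7)), 0, p), 4L)
  expect_equal(classify_bpr(c(1.000001, rep(0, 7)), 0, p), 1L)
})

test_that("NOF flags need 10% in some entity or the normal group", {
  p <- bpr_params()
  expect_true(flag_nof(c(43.48, rep(0, 8)), p))
  expect_true(flag_nof(c(7.16, 10.05, 2.35, 5.15, 6.07, 4.83, 1.67, 5.50, 3.24), p))
  expect_true(flag_nof(c(rep(0, 8), 11.81), p))  # normal alone qualifies
  expect_false(flag_nof(rep(9.99, 9), p))
})

test_that("hotspot clustering merges nearby BPRs only", {
  mk <- function(starts, ends, chrom = "1") {
    out <- tibble::tibble(chrom = chrom, start_pos = starts, end_pos = ends,
                          count_A = 1L)
    class(out) <- c("bpr_catalog", class(tibble::tibble()))
    out
  }
  p <- bpr_params()
  # two BPRs 50 kb apart cluster at the 100 kb gap cut
  h1 <- find_hotspots(mk(c(1e6, 1e6 + 51e3), c(1e6 + 1e3, 1e6 + 52e3)), p)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$n_bprs, 2L)
  # 200 kb apart: no cluster reaches two members
  h2 <- find_hotspots(mk(c(1e6, 1.201e6), c(1.0001e6, 1.2011e6)), p)
  expect_equal(nrow(h2), 0)
  # a planted chain of 4 adjacent BPRs plus one isolated BPR
  starts <- c(2e6, 2.05e6, 2.1e6, 2.15e6, 5e6)
  h3 <- find_hotspots(mk(starts, starts + 1e3), p)
  expect_equal(nrow(h3), 1)
  expect_equal(h3$n_bprs, 4L)
  expect_equal(h3$total_carriers, 4)
})
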