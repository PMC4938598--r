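# independent brute-force oracles and shared fixtures

# exhaustive O(n^2) arc scan with per-arc two-pass moments
oracle_max_arc <- function(x, mw, return_arc = TRUE) {
  n <- length(x)
  best <- -1; bi <- NA_integer_; bj <- NA_integer_
  for (i in 1:n) for (j in i:n) {
    k <- j - i + 1
    if (k < mw || n - k < mw) next
    a <- x[i:j]; b <- x[-(i:j)]
    s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n - 2)
    s <- max(sqrt(s2), 1e-8)
    z <- abs((mean(a) - mean(b)) / (s * sqrt(1 / k + 1 / (n - k))))
    # same tie tolerance as the implementation: of arcs whose |Z| are
    # mathematically equal (an arc and its complement), the first in
    # lexicographic (start, end) order is reported
    if (z > best * (1 + 1e-9)) { best <- z; bi <- i; bj <- j }
  }
  if (return_arc) list(stat = best, i = bi, j = bj) else best
}

# all permutations of a vector (rows), for full-enumeration p-values
all_perms <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], all_perms(v[-i]), deparse.level = 0)
  }))
}

oracle_perm_pvalue <- function(x, t_obs, mw) {
  pm <- all_perms(x)
  stats <- apply(pm, 1, function(r) oracle_max_arc(r, mw, return_arc = FALSE))
  mean(stats >= t_obs - 1e-12)
}

# published worked-example catalogs bundled with the package
study_group_sizes <- c(breast = 377, colorectal = 189, gastric = 340,
                       lung = 291, medulloblastoma = 1104, ovarian = 207,
                       prostate = 120, renal = 109, normal = 432)
study_entities <- setdiff(names(study_group_sizes), "normal")

read_count_catalog <- function() {
  readr::read_tsv(system.file("extdata", "recurrent_bpr_counts.tsv",
                              package = "bprscan"),
                  show_col_types = FALSE)
}

read_nof_catalog <- function() {
  readr::read_tsv(system.file("extdata", "nof_bpr_frequencies.tsv",
                              package = "bprscan"),
                  show_col_types = FALSE)
}

# small multi-entity simulation used across tests
toy_cohort_spec <- function(seed = 1L, noise_sd = 0.15, jump = 1.5,
                            n_per_group = 20L) {
  cohort_spec(
    entities = c(A = n_per_group, B = n_per_group, C = n_per_group),
    normal = c(normal = n_per_group),
    chromosomes = tibble::tibble(chrom = as.character(1:3),
                                 n_probes = 300L, spacing = 1000),
    bprs = tibble::tibble(
      chrom = c("1", "2", "3"),
      left_probe = c(100L, 120L, 80L),
      len = c(40L, 40L, 40L),
      jump = jump,
      A = c(0.3, 0.25, 0.2), B = c(0, 0.25, 0.2), C = c(0, 0, 0.2),
      normal = c(0, 0, 0.3)),
    noise_sd = noise_sd, seed = seed)
}
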