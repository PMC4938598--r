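#' Segmentation parameters
#'
#' Tuning knobs for the circular-binary-segmentation stage. The defaults
#' follow the standard settings for SNP-array copy-number segmentation:
#' split significance `alpha = 0.001`, `min_width = 4` markers per segment,
#' `undo_sd = 0.5` noise-sd units for post-hoc pruning of weak change-points,
#' and a 10-marker outlier-smoothing window.
#'
#' @param alpha Split significance level, in (0, 1).
#' @param n_perm Permutations per split test (>= 100). When the stretch is so
#'   short that `factorial(n) <= n_perm`, the permutation distribution is
#'   enumerated exactly instead of sampled.
#' @param min_width Minimal markers per segment (>= 2).
#' @param undo_sd Pruning threshold in noise-sd units (>= 0; 0 disables).
#' @param smooth_region Neighbor window, in markers, for outlier detection.
#' @param outlier_sd Distance to the nearest neighbor value, in noise-sd
#'   units, beyond which a marker is treated as an outlier.
#' @param shrink_sd Shrink target for outliers, in noise-sd units.
#' @param seed Integer seed controlling the permutation draws.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(alpha = 0.001, n_perm = 10000L, min_width = 4L,
                                undo_sd = 0.5, smooth_region = 10L,
                                outlier_sd = 4, shrink_sd = 2, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, min_width >= 2, n_perm >= 100, undo_sd >= 0,
            smooth_region >= 1, outlier_sd > 0, shrink_sd >= 0)
  structure(list(alpha = alpha, n_perm = as.integer(n_perm),
                 min_width = as.integer(min_width), undo_sd = undo_sd,
                 smooth_region = as.integer(smooth_region),
                 outlier_sd = outlier_sd, shrink_sd = shrink_sd,
                 seed = as.integer(seed)),
            class = "segmentation_params")
}

#' Robust noise-sd estimate from lag-1 differences
#'
#' `median(|x[i+1] - x[i]|) / (0.6745 * sqrt(2))`, the MAD-based estimator of
#' the per-marker noise sd. Robust to true change-points because only the few
#' differences straddling a boundary are inflated. Floored at 1e-8 so that
#' noise-free inputs remain usable downstream.
#'
#' @param x Ordered numeric marker values (>= 2).
#' @return Positive scalar sd estimate.
#' @export
estimate_noise_sd <- function(x) {
  if (length(x) < 2) stop_bprscan("need at least 2 markers to estimate noise")
  max(median(abs(diff(x))) / (0.6745 * sqrt(2)), 1e-8)
}

#' Detect and shrink outlier markers
#'
#' A marker is an outlier when its distance to the nearest neighboring value
#' within `smooth_region` markers on either side exceeds `outlier_sd * sd`;
#' it is then moved to that nearest neighbor value plus `shrink_sd * sd`
#' toward its original value. Decisions use the original values throughout,
#' so a genuine short level of two or more similar markers is retained (each
#' member has a near neighbor).
#'
#' @param x Ordered numeric marker values.
#' @param params A [segmentation_params()].
#' @param noise_sd Noise sd; estimated from `x` by default.
#' @return Numeric vector of the same length.
#' @export
smooth_outliers <- function(x, params = segmentation_params(),
                            noise_sd = estimate_noise_sd(x)) {
  n <- length(x)
  if (n < 2) return(x)
  w <- params$smooth_region
  out <- x
  for (i in seq_len(n)) {
    nb <- c(seq(max(1, i - w), i - 1), seq(i + 1, min(n, i + w)))
    nb <- nb[nb >= 1 & nb <= n & nb != i]
    d <- abs(x[nb] - x[i])
    k <- which.min(d)
    if (d[k] > params$outlier_sd * noise_sd) {
      nn <- x[nb[k]]
      out[i] <- nn + sign(x[i] - nn) * params$shrink_sd * noise_sd
    }
  }
  out
}

#' Maximal t-like statistic over circular arcs
#'
#' Scans every circular arc with at least `min_width` markers whose
#' complement also has at least `min_width` markers, and returns the maximal
#' absolute two-sample t-like statistic
#' `Z = (mean_arc - mean_complement) / (s * sqrt(1/k + 1/(n-k)))`
#' with `s` the pooled within-split sd, together with the maximizing arc
#' (ties broken to the smallest start, then smallest end index).
#'
#' @param x Ordered numeric marker values.
#' @param min_width Minimal markers per arc and per complement.
#' @return List with `stat`, `arc_start`, `arc_end` (1-based marker indices)
#'   and `tested`. When fewer than `2 * min_width` markers are supplied no
#'   test is possible and `tested` is `FALSE` with `stat = NA`.
#' @export
max_arc_statistic <- function(x, min_width = 4L) {
  if (length(x) < 2 * min_width) {
    return(list(stat = NA_real_, arc_start = NA_integer_,
                arc_end = NA_integer_, tested = FALSE))
  }
  res <- cpp_max_arc_stat(as.numeric(x), as.integer(min_width))
  list(stat = res$stat, arc_start = res$arc_start, arc_end = res$arc_end,
       tested = TRUE)
}

#' Permutation p-value for a split statistic
#'
#' Reference distribution of the maximal arc statistic under random
#' reordering of the markers. When all `factorial(n)` orderings number no
#' more than `n_perm` they are enumerated exactly and
#' `p = #\{T >= T_obs\} / n!`; otherwise `n_perm` uniform permutations are
#' drawn (from R's RNG; seed it for reproducibility) and
#' `p = (1 + #\{T >= T_obs\}) / (1 + n_perm)`, with an early exit once the
#' exceedance count already forces `p > alpha`.
#'
#' @param x Ordered numeric marker values the statistic was computed on.
#' @param t_obs Observed statistic from [max_arc_statistic()].
#' @param params A [segmentation_params()].
#' @return List with `p`, `n_used`, `exceed`, `exact`, `early`.
#' @export
permutation_pvalue <- function(x, t_obs, params = segmentation_params()) {
  n <- length(x)
  if (n <= 10 && factorial(n) <= params$n_perm) {
    res <- cpp_perm_pvalue_exact(as.numeric(x), t_obs, params$min_width)
    return(list(p = res$p, n_used = res$n_used, exceed = res$exceed,
                exact = TRUE, early = FALSE))
  }
  res <- cpp_perm_pvalue_mc(as.numeric(x), t_obs, params$min_width,
                            params$n_perm, params$alpha)
  list(p = res$p, n_used = res$n_used, exceed = res$exceed,
       exact = FALSE, early = res$early)
}

# deterministic per-stretch seed so that results do not depend on the order
# in which samples/stretches are visited
stretch_seed <- function(seed, s, e, salt = 0L) {
  as.integer((as.double(seed) + 1009 * s + e + 104729 * salt) %% 2147483647)
}

#' Segment one chromosome by circular binary segmentation
#'
#' Recursively tests each stretch with [max_arc_statistic()] and
#' [permutation_pvalue()]; when `p <= alpha` the stretch is cut at the
#' accepted arc boundaries (an interior arc yields two change-points, an arc
#' touching an end one) and the pieces are re-tested, stopping when no split
#' is significant or a piece is shorter than `2 * min_width`. A boundary
#' whose flank would be shorter than `min_width` is dropped (the flank is
#' absorbed into the arc), so every reported segment has at least
#' `min_width` markers unless the chromosome itself is shorter. Weak
#' change-points are then pruned with [sd_undo()].
#'
#' @param x Ordered numeric log2 ratios (smoothed upstream if desired).
#' @param positions Strictly increasing base-pair positions, same length.
#' @param params A [segmentation_params()].
#' @param seed_salt Integer mixed into the per-stretch permutation seeds
#'   (used by [segment_profile()] to decorrelate samples).
#' @return Tibble of segments: `start_idx`, `end_idx`, `start_pos`,
#'   `end_pos`, `n_markers`, `seg_mean`, tiling the markers exactly.
#' @export
segment_chromosome <- function(x, positions, params = segmentation_params(),
                               seed_salt = 0L) {
  n <- length(x)
  stopifnot(length(positions) == n)
  if (n > 1 && any(diff(positions) <= 0)) {
    stop_bprscan("positions must be strictly increasing")
  }
  if (n < params$min_width) {
    warning("stretch shorter than min_width; kept as a single segment")
    return(segments_from_cuts(x, positions, integer(0)))
  }
  cuts <- cbs_recurse(x, 1L, n, params, seed_salt)
  segs <- segments_from_cuts(x, positions, sort(cuts))
  if (params$undo_sd > 0 && nrow(segs) > 1) {
    segs <- sd_undo(segs, x, params$undo_sd, noise_sd = estimate_noise_sd(x))
  }
  segs
}

# returns global cut indices: a cut at c means a boundary between markers
# c and c+1
cbs_recurse <- function(x, s, e, params, salt) {
  len <- e - s + 1L
  if (len < 2L * params$min_width) return(integer(0))
  xs <- x[s:e]
  arc <- max_arc_statistic(xs, params$min_width)
  pv <- withr::with_seed(
    stretch_seed(params$seed, s, e, salt),
    permutation_pvalue(xs, arc$stat, params)
  )
  if (pv$p > params$alpha) return(integer(0))
  i <- s + arc$arc_start - 1L
  j <- s + arc$arc_end - 1L
  cuts <- integer(0)
  if (i > s && (i - s) >= params$min_width) cuts <- c(cuts, i - 1L)
  if (j < e && (e - j) >= params$min_width) cuts <- c(cuts, j)
  if (length(cuts) == 0) return(integer(0))
  bounds <- c(s - 1L, cuts, e)
  out <- cuts
  for (p in seq_len(length(bounds) - 1L)) {
    out <- c(out, cbs_recurse(x, bounds[p] + 1L, bounds[p + 1L], params, salt))
  }
  out
}

segments_from_cuts <- function(x, positions, cuts) {
  n <- length(x)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  tibble(
    start_idx = starts, end_idx = ends,
    start_pos = positions[starts], end_pos = positions[ends],
    n_markers = ends - starts + 1L,
    seg_mean = vapply(seq_along(starts),
                      function(k) mean(x[starts[k]:ends[k]]), numeric(1))
  )
}

#' Prune weak change-points (sd-undo)
#'
#' Iteratively removes the change-point with the smallest adjacent
#' segment-mean gap, in noise-sd units, among those below `undo_sd`; the two
#' segments are merged and the merged mean recomputed from the marker
#' values. Stops when every adjacent pair differs by at least
#' `undo_sd * noise_sd`.
#'
#' @param segments Segment tibble tiling `x` (from [segment_chromosome()]).
#' @param x The marker values the segments tile.
#' @param undo_sd Threshold in noise-sd units.
#' @param noise_sd Noise sd; estimated from `x` by default.
#' @return Segment tibble, never with more rows than the input.
#' @export
sd_undo <- function(segments, x, undo_sd, noise_sd = estimate_noise_sd(x)) {
  if (nrow(segments) < 2 || undo_sd <= 0) return(segments)
  starts <- segments$start_idx
  ends <- segments$end_idx
  means <- segments$seg_mean
  repeat {
    gaps <- abs(diff(means)) / noise_sd
    k <- which.min(gaps)
    if (length(gaps) == 0 || gaps[k] >= undo_sd) break
    merged_mean <- mean(x[starts[k]:ends[k + 1]])
    starts <- starts[-(k + 1)]
    means[k] <- merged_mean
    means <- means[-(k + 1)]
    ends <- ends[-k]
    if (length(means) == 1) break
  }
  tibble(
    start_idx = starts, end_idx = ends,
    start_pos = segments$start_pos[match(starts, segments$start_idx)],
    end_pos = segments$end_pos[match(ends, segments$end_idx)],
    n_markers = ends - starts + 1L,
    seg_mean = means
  )
}

#' Segment every sample of a ratio-scale cohort
#'
#' Applies outlier smoothing and [segment_chromosome()] per sample and
#' chromosome. Samples are independent: results do not depend on processing
#' order (each stretch's permutation seed is derived from the global seed,
#' the stretch coordinates and a per-sample/chromosome salt).
#'
#' @param sm A ratio-scale [signal_matrix()].
#' @param params A [segmentation_params()].
#' @param smooth Apply [smooth_outliers()] first (default `TRUE`).
#' @return A `segmentation_profile` tibble: `sample`, `chrom`, `start_idx`,
#'   `end_idx`, `start_pos`, `end_pos`, `n_markers`, `seg_mean`, with the
#'   per-sample noise-sd estimates in `attr(, "noise_sd")`.
#' @export
segment_profile <- function(sm, params = segmentation_params(), smooth = TRUE) {
  stopifnot(inherits(sm, "signal_matrix"))
  if (sm$scale != "ratio") {
    stop_bprscan("segmentation expects log2-ratio-scale signals")
  }
  pm <- sm$probe_map
  chroms <- unique(pm$chrom)
  samples <- colnames(sm$values)
  noise <- list()
  res <- vector("list", length(samples) * length(chroms))
  k <- 0L
  for (si in seq_along(samples)) {
    for (ci in seq_along(chroms)) {
      idx <- which(pm$chrom == chroms[ci])
      x <- sm$values[idx, si]
      nsd <- estimate_noise_sd(x)
      if (smooth) x <- smooth_outliers(x, params, noise_sd = nsd)
      salt <- (si - 1L) * length(chroms) + ci
      segs <- segment_chromosome(x, pm$pos[idx], params, seed_salt = salt)
      k <- k + 1L
      res[[k]] <- dplyr::mutate(segs, sample = samples[si],
                                chrom = chroms[ci], .before = 1)
      noise[[paste(samples[si], chroms[ci], sep = ".")]] <- nsd
    }
  }
  out <- dplyr::bind_rows(res)
  attr(out, "noise_sd") <- unlist(noise)
  class(out) <- c("segmentation_profile", class(out))
  out
}

#' @method glance segmentation_profile
#' @export
glance.segmentation_profile <- function(x, ...) {
  tibble(
    n_samples = dplyr::n_distinct(x$sample),
    n_chromosomes = dplyr::n_distinct(x$chrom),
    n_segments = nrow(x),
    median_markers = median(x$n_markers),
    mean_noise_sd = mean(attr(x, "noise_sd") %||% NA_real_)
  )
}

#' @method tidy segmentation_profile
#' @export
tidy.segmentation_profile <- function(x, ...) {
  as_tibble(x)
}
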