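#' Design a synthetic multi-entity cohort
#'
#' Describes a cohort of piecewise-constant log2-ratio profiles with planted
#' copy-number segments whose boundaries recur across samples at configured
#' per-group probabilities. The default group sizes mirror a large
#' multi-entity SNP-array study (eight tumor entities plus a normal group:
#' 377, 189, 340, 291, 1104, 207, 120, 109 and 432 samples), scalable by
#' `scale` for fast tests. The default probe layout is a compact one (4
#' chromosomes, 2,000 probes each, 1 kb spacing) sized for testing; pass a
#' custom `chromosomes` table for larger layouts.
#'
#' Planted breakpoints fall between consecutive probes, so the detectable
#' breakpoint-region for a boundary between probe `i` and `i+1` is the
#' interval (position of probe `i`, position of probe `i+1`).
#'
#' @param entities Named integer vector of tumor-entity sample sizes.
#' @param normal Named integer vector of length 1: the normal group.
#' @param scale Positive factor applied to all group sizes (rounded up to at
#'   least 1 sample per group).
#' @param chromosomes Tibble with columns `chrom`, `n_probes`, `spacing`.
#' @param bprs Tibble of planted breakpoint regions: columns `chrom`,
#'   `left_probe` (the boundary sits between this probe index and the next),
#'   `len` (elevated segment length in probes), `jump` (log2 shift, > 0),
#'   plus one probability column per group (named as the group; missing
#'   groups default to 0). Each planted segment contributes two recurrent
#'   boundaries: at its start and at its end.
#' @param noise_sd Per-probe Gaussian noise sd on the log2 scale (default
#'   0.15, well below the 0.6 breakpoint threshold).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(entities = c(breast = 377, colorectal = 189,
                                     gastric = 340, lung = 291,
                                     medulloblastoma = 1104, ovarian = 207,
                                     prostate = 120, renal = 109),
                        normal = c(normal = 432),
                        scale = 1,
                        chromosomes = tibble(chrom = as.character(1:4),
                                             n_probes = 2000L,
                                             spacing = 1000),
                        bprs = NULL,
                        noise_sd = 0.15,
                        seed = 1L) {
  stopifnot(length(normal) == 1, !is.null(names(entities)), scale > 0)
  entities <- setNames(pmax(1L, as.integer(ceiling(entities * scale))),
                       names(entities))
  normal <- setNames(pmax(1L, as.integer(ceiling(normal * scale))),
                     names(normal))
  groups <- c(entities, normal)
  if (any(groups < 1)) stop_bprscan("all group sizes must be >= 1")
  chromosomes <- as_tibble(chromosomes)
  chromosomes$chrom <- norm_chrom(chromosomes$chrom)
  if (is.null(bprs)) {
    bprs <- tibble(chrom = character(0), left_probe = integer(0),
                   len = integer(0), jump = numeric(0))
  }
  bprs <- as_tibble(bprs)
  if (nrow(bprs) > 0) {
    bprs$chrom <- norm_chrom(bprs$chrom)
    for (g in names(groups)) {
      if (!g %in% names(bprs)) bprs[[g]] <- 0
    }
    probs <- as.matrix(bprs[, names(groups), drop = FALSE])
    if (any(probs < 0 | probs > 1)) {
      stop_bprscan("presence probabilities must lie in [0, 1]")
    }
    if (any(bprs$jump <= 0)) stop_bprscan("jump magnitudes must be > 0")
    if (any(bprs$len < 1)) stop_bprscan("planted segment length must be >= 1")
    for (ch in unique(bprs$chrom)) {
      b <- bprs[bprs$chrom == ch, ]
      npr <- chromosomes$n_probes[chromosomes$chrom == ch]
      if (length(npr) != 1) stop_bprscan("planted BPR on unknown chromosome ", ch)
      if (any(b$left_probe < 1 | b$left_probe + b$len + 1 > npr)) {
        stop_bprscan("planted segment exceeds chromosome ", ch, " probe range")
      }
      # spans including their flanking boundary probes must not touch,
      # otherwise the planted truth is ambiguous
      b <- b[order(b$left_probe), ]
      lo <- b$left_probe
      hi <- b$left_probe + b$len + 1
      if (nrow(b) > 1 && any(lo[-1] <= hi[-nrow(b)])) {
        stop_bprscan("planted segments overlap on chromosome ", ch)
      }
    }
    bprs$bpr_id <- paste0("bpr", seq_len(nrow(bprs)))
  }
  structure(
    list(entities = entities, normal = normal, groups = groups,
         chromosomes = chromosomes, bprs = bprs,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Read a cohort design from a YAML file
#'
#' The YAML mirrors the arguments of [cohort_spec()]: maps `entities` and
#' `normal`, tables `chromosomes` and `bprs` (lists of records), scalars
#' `noise_sd`, `seed`, `scale`.
#'
#' @param path Path to a YAML file.
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$entities)) args$entities <- unlist(y$entities)
  if (!is.null(y$normal)) args$normal <- unlist(y$normal)
  if (!is.null(y$scale)) args$scale <- y$scale
  if (!is.null(y$chromosomes)) args$chromosomes <- dplyr::bind_rows(y$chromosomes)
  if (!is.null(y$bprs)) args$bprs <- dplyr::bind_rows(y$bprs)
  if (!is.null(y$noise_sd)) args$noise_sd <- y$noise_sd
  if (!is.null(y$seed)) args$seed <- y$seed
  do.call(cohort_spec, args)
}

probe_map_from_spec <- function(spec) {
  as_probe_map(dplyr::bind_rows(lapply(seq_len(nrow(spec$chromosomes)), function(i) {
    ch <- spec$chromosomes$chrom[i]
    np <- spec$chromosomes$n_probes[i]
    sp <- spec$chromosomes$spacing[i]
    tibble(probe_id = sprintf("p%s_%d", ch, seq_len(np)),
           chrom = ch, pos = sp * seq_len(np))
  })))
}

#' Simulate a cohort of log2-ratio profiles with planted breakpoints
#'
#' Each sample starts from i.i.d. Gaussian probe noise around 0; each planted
#' segment is independently present with its group's probability, and when
#' present shifts the profile by `jump` log2 units over its probe span. All
#' samples share one probe layout, so recurrent boundaries coincide exactly
#' across carriers. Fully reproducible from the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort_sim` list: `signal` (a ratio-scale [signal_matrix()]),
#'   `probe_map`, `groups` (tibble `sample`, `group`), `group_sizes`,
#'   `truth` (list with `presence`, per-group `counts`, planted `segments`
#'   and boundary intervals `boundaries`), and the `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  pm <- probe_map_from_spec(spec)
  group_names <- names(spec$groups)
  groups <- dplyr::bind_rows(lapply(group_names, function(g) {
    tibble(sample = sprintf("%s_%03d", g, seq_len(spec$groups[[g]])), group = g)
  }))
  n_samples <- nrow(groups)
  n_probes <- nrow(pm)
  # probe-index offsets per chromosome within the concatenated map
  offs <- cumsum(c(0, spec$chromosomes$n_probes))[seq_len(nrow(spec$chromosomes))]
  names(offs) <- spec$chromosomes$chrom

  withr::with_seed(spec$seed, {
    vals <- if (spec$noise_sd > 0) {
      matrix(rnorm(n_probes * n_samples, sd = spec$noise_sd),
             nrow = n_probes, ncol = n_samples)
    } else {
      matrix(0, nrow = n_probes, ncol = n_samples)
    }
    presence <- NULL
    if (nrow(spec$bprs) > 0) {
      presence <- dplyr::bind_rows(lapply(seq_len(nrow(spec$bprs)), function(b) {
        row <- spec$bprs[b, ]
        pr <- unlist(row[group_names])[groups$group]
        tibble(sample = groups$sample, group = groups$group,
               bpr_id = row$bpr_id,
               present = rbinom(n_samples, 1L, pr) == 1L)
      }))
      for (b in seq_len(nrow(spec$bprs))) {
        row <- spec$bprs[b, ]
        idx <- offs[[row$chrom]] + (row$left_probe + 1):(row$left_probe + row$len)
        carriers <- which(presence$present[presence$bpr_id == row$bpr_id])
        vals[idx, carriers] <- vals[idx, carriers] + row$jump
      }
    }
  })
  rownames(vals) <- pm$probe_id
  colnames(vals) <- groups$sample

  truth <- list(presence = presence %||% tibble(sample = character(0),
                                                group = character(0),
                                                bpr_id = character(0),
                                                present = logical(0)))
  if (nrow(spec$bprs) > 0) {
    truth$counts <- truth$presence |>
      dplyr::filter(.data$present) |>
      dplyr::count(.data$bpr_id, .data$group, name = "carriers")
    truth$segments <- truth$presence |>
      dplyr::filter(.data$present) |>
      dplyr::left_join(spec$bprs, by = "bpr_id") |>
      dplyr::transmute(.data$sample, .data$group, .data$bpr_id, .data$chrom,
                       first_probe = .data$left_probe + 1L,
                       last_probe = .data$left_probe + .data$len,
                       true_mean = .data$jump)
    truth$boundaries <- planted_boundaries(spec, pm)
  } else {
    truth$counts <- tibble(bpr_id = character(0), group = character(0),
                           carriers = integer(0))
    truth$segments <- tibble(sample = character(0))
    truth$boundaries <- tibble(bpr_id = character(0))
  }

  structure(
    list(signal = signal_matrix(vals, pm, scale = "ratio"),
         probe_map = pm, groups = groups, group_sizes = spec$groups,
         truth = truth, spec = spec),
    class = "cohort_sim"
  )
}

# the two boundary intervals each planted segment generates
planted_boundaries <- function(spec, pm) {
  dplyr::bind_rows(lapply(seq_len(nrow(spec$bprs)), function(b) {
    row <- spec$bprs[b, ]
    pos <- pm$pos[pm$chrom == row$chrom]
    tibble(bpr_id = row$bpr_id, chrom = row$chrom,
           side = c("start", "end"),
           start_pos = c(pos[row$left_probe], pos[row$left_probe + row$len]),
           end_pos = c(pos[row$left_probe + 1], pos[row$left_probe + row$len + 1]))
  }))
}

#' Expected BPR frequency table from planted truth
#'
#' Converts a simulation's realized carrier counts into the catalog the
#' pipeline should recover: one row per planted boundary interval with
#' per-group carrier counts and percent frequencies (100 * count / group
#' size), for direct comparison with [aggregate_catalog()] output.
#'
#' @param sim A `cohort_sim` from [simulate_cohort()].
#' @return A tibble with `bpr_id`, `side`, `chrom`, `start_pos`, `end_pos`,
#'   one `count_<group>` and one `freq_<group>` column per group.
#' @export
truth_to_expected_catalog <- function(sim) {
  stopifnot(inherits(sim, "cohort_sim"))
  if (nrow(sim$spec$bprs) == 0) return(tibble())
  counts <- tidyr::pivot_wider(sim$truth$counts,
                               names_from = "group", values_from = "carriers",
                               values_fill = 0L)
  for (g in names(sim$group_sizes)) {
    if (!g %in% names(counts)) counts[[g]] <- 0L
  }
  out <- dplyr::left_join(sim$truth$boundaries, counts, by = "bpr_id")
  for (g in names(sim$group_sizes)) {
    out[[paste0("freq_", g)]] <- 100 * out[[g]] / sim$group_sizes[[g]]
    names(out)[names(out) == g] <- paste0("count_", g)
  }
  out
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("<cohort_sim> ", nrow(x$groups), " samples in ",
      length(x$group_sizes), " groups, ", nrow(x$probe_map), " probes, ",
      nrow(x$spec$bprs), " planted BPR segment(s)\n", sep = "")
  invisible(x)
}
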