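#' Breakpoint-region parameters
#'
#' @param jump_threshold Adjacent segment-mean difference, in log2 units,
#'   above which the inter-segment stretch is a breakpoint region. Strict
#'   `>`; the default 0.6 corresponds to about one copy on the log2 scale.
#' @param class_entity_freq Percent frequency at which a BPR "occurs" in an
#'   entity (default 1).
#' @param class_entity_fraction Fraction of entities required for the
#'   cancer-specific/common classes (default 0.25).
#' @param class_normal_freq Percent normal frequency separating
#'   cancer-specific from common (default 0.5).
#' @param nof_freq Percent frequency for the noticeable-occurrence-frequency
#'   flag (default 10).
#' @param hotspot_gap Maximal base-pair gap between clustered BPR intervals
#'   (default 100 kb).
#' @param hotspot_min_members Minimal distinct BPRs per reported hotspot.
#' @return A `bpr_params` list.
#' @export
bpr_params <- function(jump_threshold = 0.6, class_entity_freq = 1,
                       class_entity_fraction = 0.25, class_normal_freq = 0.5,
                       nof_freq = 10, hotspot_gap = 1e5,
                       hotspot_min_members = 2L) {
  stopifnot(jump_threshold > 0,
            class_entity_freq >= 0, class_entity_freq <= 100,
            class_normal_freq >= 0, class_normal_freq <= 100,
            nof_freq >= 0, nof_freq <= 100,
            class_entity_fraction > 0, class_entity_fraction <= 1,
            hotspot_gap >= 0, hotspot_min_members >= 1)
  structure(list(jump_threshold = jump_threshold,
                 class_entity_freq = class_entity_freq,
                 class_entity_fraction = class_entity_fraction,
                 class_normal_freq = class_normal_freq,
                 nof_freq = nof_freq, hotspot_gap = hotspot_gap,
                 hotspot_min_members = as.integer(hotspot_min_members)),
            class = "bpr_params")
}

#' Detect per-sample breakpoint regions
#'
#' For every pair of adjacent segments on a chromosome whose segment means
#' differ by strictly more than `jump_threshold`, the genomic stretch
#' between the last probe of the left segment and the first probe of the
#' right segment is emitted as a breakpoint region. A sample contributes at
#' most one carrier mark per distinct interval.
#'
#' @param profile A `segmentation_profile` (one or many samples).
#' @param params A [bpr_params()].
#' @return A tibble `sample`, `chrom`, `start_pos`, `end_pos`.
#' @export
detect_bprs <- function(profile, params = bpr_params()) {
  profile |>
    dplyr::group_by(.data$sample, .data$chrom) |>
    dplyr::arrange(.data$start_idx, .by_group = TRUE) |>
    dplyr::mutate(next_mean = dplyr::lead(.data$seg_mean),
                  next_start = dplyr::lead(.data$start_pos)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$next_mean),
                  abs(.data$seg_mean - .data$next_mean) > params$jump_threshold) |>
    dplyr::transmute(.data$sample, .data$chrom,
                     start_pos = .data$end_pos, end_pos = .data$next_start) |>
    dplyr::distinct()
}

#' Aggregate per-sample BPRs into a cohort catalog
#'
#' BPR intervals are matched across samples by exact (chromosome, start,
#' end) identity — all samples share one probe layout, so recurrent
#' breakpoints land on identical probe pairs. Carrier counts are tallied per
#' group; the cancer total is the sum over all tumor entities.
#'
#' @param sample_bprs Tibble from [detect_bprs()].
#' @param groups Tibble `sample`, `group` covering every sample.
#' @param group_sizes Named integer vector of group sizes (all groups,
#'   including samples that carried no BPR).
#' @param normal_group Name of the normal group within `group_sizes`.
#' @return A `bpr_catalog` tibble: `chrom`, `start_pos`, `end_pos`, one
#'   `count_<group>` column per group, and `cancer_total`.
#' @export
aggregate_catalog <- function(sample_bprs, groups, group_sizes,
                              normal_group = "normal") {
  unknown <- setdiff(unique(sample_bprs$sample), groups$sample)
  if (length(unknown) > 0) {
    stop_bprscan("sample(s) without group assignment: ",
                 paste(head(unknown, 5), collapse = ", "))
  }
  if (!normal_group %in% names(group_sizes)) {
    stop_bprscan("normal group '", normal_group, "' not in group_sizes")
  }
  entities <- setdiff(names(group_sizes), normal_group)
  counts <- sample_bprs |>
    dplyr::distinct(.data$sample, .data$chrom, .data$start_pos, .data$end_pos) |>
    dplyr::left_join(groups, by = "sample") |>
    dplyr::count(.data$chrom, .data$start_pos, .data$end_pos, .data$group) |>
    tidyr::pivot_wider(names_from = "group", values_from = "n",
                       values_fill = 0L, names_prefix = "count_")
  for (g in names(group_sizes)) {
    col <- paste0("count_", g)
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  counts <- counts[, c("chrom", "start_pos", "end_pos",
                       paste0("count_", c(entities, normal_group)))]
  counts$cancer_total <- as.integer(
    rowSums(counts[, paste0("count_", entities), drop = FALSE]))
  counts <- counts[order(as.integer(counts$chrom), counts$start_pos,
                         counts$end_pos), ]
  attr(counts, "group_sizes") <- group_sizes
  attr(counts, "normal_group") <- normal_group
  attr(counts, "entities") <- entities
  class(counts) <- c("bpr_catalog", class(tibble()))
  counts
}

#' Add percent frequencies to a BPR catalog
#'
#' `freq = 100 * count / group size`, carried unrounded; use
#' `round_frequencies()` (or [write_result_tables()]) for the 2-decimal
#' half-away-from-zero display convention.
#'
#' @param catalog A `bpr_catalog` from [aggregate_catalog()].
#' @param group_sizes Named sizes; defaults to those stored on the catalog.
#' @return The catalog with one `freq_<group>` column per group.
#' @export
frequency_table <- function(catalog, group_sizes = attr(catalog, "group_sizes")) {
  if (any(group_sizes <= 0)) stop_bprscan("group sizes must be positive")
  for (g in names(group_sizes)) {
    cc <- paste0("count_", g)
    if (!cc %in% names(catalog)) stop_bprscan("catalog lacks column ", cc)
    catalog[[paste0("freq_", g)]] <- 100 * catalog[[cc]] / group_sizes[[g]]
  }
  catalog
}

#' Round catalog frequencies for display
#' @param catalog Catalog with `freq_*` columns.
#' @param digits Decimal places (default 2), half rounded away from zero.
#' @export
round_frequencies <- function(catalog, digits = 2) {
  fc <- grep("^freq_", names(catalog), value = TRUE)
  for (col in fc) catalog[[col]] <- round_half_away(catalog[[col]], digits)
  catalog
}

#' Classify one BPR into the four recurrency classes
#'
#' With `k` the number of tumor entities in which the BPR occurs (frequency
#' `>= class_entity_freq`): class 4 when `k = 0`; class 1 (entity-specific)
#' when `k = 1`, regardless of the normal frequency; otherwise class 2
#' (cancer-specific) when `k / n_entities >= class_entity_fraction` and the
#' normal frequency is below `class_normal_freq`, class 3 (common) when the
#' normal frequency reaches it. When `k >= 2` entities qualify but their
#' fraction stays below the cut (possible only with more than 8 entities at
#' the defaults), the scheme leaves no label; class 4 is returned with a
#' warning.
#'
#' @param entity_freqs Numeric vector of per-entity percent frequencies
#'   (unrounded).
#' @param normal_freq Percent frequency in the normal group.
#' @param params A [bpr_params()].
#' @return Integer class in 1..4.
#' @export
classify_bpr <- function(entity_freqs, normal_freq, params = bpr_params()) {
  k <- sum(entity_freqs >= params$class_entity_freq)
  if (k == 0) return(4L)
  if (k == 1) return(1L)
  if (k / length(entity_freqs) >= params$class_entity_fraction) {
    if (normal_freq < params$class_normal_freq) return(2L) else return(3L)
  }
  warning("BPR occurs in ", k, " entities but below the entity-fraction cut; ",
          "no class defined, reporting 4")
  4L
}

#' Flag noticeable occurrence frequency (NOF)
#'
#' `TRUE` iff any tumor entity or the normal group reaches `nof_freq`
#' percent.
#'
#' @param freqs Numeric vector of percent frequencies across all groups
#'   (entities and normal).
#' @param params A [bpr_params()].
#' @return Logical scalar.
#' @export
flag_nof <- function(freqs, params = bpr_params()) {
  any(freqs >= params$nof_freq)
}

#' Classify and flag every BPR of a catalog
#'
#' @param catalog Catalog with frequencies (see [frequency_table()]).
#' @param params A [bpr_params()].
#' @return The catalog with `class` and `nof` columns.
#' @export
classify_catalog <- function(catalog, params = bpr_params()) {
  entities <- attr(catalog, "entities")
  normal_group <- attr(catalog, "normal_group")
  ef <- as.matrix(catalog[, paste0("freq_", entities), drop = FALSE])
  nf <- catalog[[paste0("freq_", normal_group)]]
  catalog$class <- vapply(seq_len(nrow(catalog)), function(i) {
    classify_bpr(ef[i, ], nf[i], params)
  }, integer(1))
  catalog$nof <- vapply(seq_len(nrow(catalog)), function(i) {
    flag_nof(c(ef[i, ], nf[i]), params)
  }, logical(1))
  catalog
}

#' Cluster BPRs into hotspot areas
#'
#' Merges BPR intervals on the same chromosome whose gaps are at most
#' `hotspot_gap` base pairs into maximal clusters and reports clusters with
#' at least `hotspot_min_members` distinct BPRs.
#'
#' @param catalog A `bpr_catalog` (frequencies/classes optional).
#' @param params A [bpr_params()].
#' @return A tibble `chrom`, `start_pos`, `end_pos`, `n_bprs`,
#'   `total_carriers`.
#' @export
find_hotspots <- function(catalog, params = bpr_params()) {
  count_cols <- grep("^count_", names(catalog), value = TRUE)
  carriers <- if (length(count_cols) > 0) {
    rowSums(catalog[, count_cols, drop = FALSE])
  } else {
    rep(0, nrow(catalog))
  }
  out <- list()
  for (ch in unique(catalog$chrom)) {
    idx <- which(catalog$chrom == ch)
    idx <- idx[order(catalog$start_pos[idx], catalog$end_pos[idx])]
    if (length(idx) == 0) next
    cl_id <- integer(length(idx))
    cl_id[1] <- 1L
    max_end <- catalog$end_pos[idx[1]]
    for (i in seq_along(idx)[-1]) {
      gap <- catalog$start_pos[idx[i]] - max_end
      if (gap <= params$hotspot_gap) {
        cl_id[i] <- cl_id[i - 1]
        max_end <- max(max_end, catalog$end_pos[idx[i]])
      } else {
        cl_id[i] <- cl_id[i - 1] + 1L
        max_end <- catalog$end_pos[idx[i]]
      }
    }
    for (cl in unique(cl_id)) {
      m <- idx[cl_id == cl]
      if (length(m) < params$hotspot_min_members) next
      out[[length(out) + 1]] <- tibble(
        chrom = ch,
        start_pos = min(catalog$start_pos[m]),
        end_pos = max(catalog$end_pos[m]),
        n_bprs = length(m),
        total_carriers = sum(carriers[m])
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(0), start_pos = numeric(0),
                  end_pos = numeric(0), n_bprs = integer(0),
                  total_carriers = numeric(0)))
  }
  dplyr::bind_rows(out)
}

#' @method tidy bpr_catalog
#' @export
tidy.bpr_catalog <- function(x, ...) {
  fc <- grep("^freq_", names(x), value = TRUE)
  if (length(fc) == 0) x <- frequency_table(x)
  fc <- grep("^freq_", names(x), value = TRUE)
  tidyr::pivot_longer(
    as_tibble(x)[, c("chrom", "start_pos", "end_pos", fc)],
    cols = dplyr::all_of(fc),
    names_to = "group", names_prefix = "freq_", values_to = "freq"
  )
}

#' @method glance bpr_catalog
#' @export
glance.bpr_catalog <- function(x, ...) {
  tibble(
    n_bprs = nrow(x),
    n_class1 = if ("class" %in% names(x)) sum(x$class == 1) else NA_integer_,
    n_class2 = if ("class" %in% names(x)) sum(x$class == 2) else NA_integer_,
    n_class3 = if ("class" %in% names(x)) sum(x$class == 3) else NA_integer_,
    n_class4 = if ("class" %in% names(x)) sum(x$class == 4) else NA_integer_,
    n_nof = if ("nof" %in% names(x)) sum(x$nof) else NA_integer_,
    total_cancer_carriers = sum(x$cancer_total)
  )
}
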