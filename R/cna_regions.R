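#' CNA-calling parameters
#'
#' @param threshold Deviation from the chromosomal mean at which a probe run
#'   is called altered: gains at `>= +threshold`, losses at `<= -threshold`
#'   (default 0.1, both cuts inclusive).
#' @param min_markers_per_region Minimum probes per reported region.
#' @return A `cna_params` list.
#' @export
cna_params <- function(threshold = 0.1, min_markers_per_region = 1L) {
  stopifnot(threshold > 0, min_markers_per_region >= 1)
  structure(list(threshold = threshold,
                 min_markers_per_region = as.integer(min_markers_per_region)),
            class = "cna_params")
}

#' Entity-averaged per-probe profile
#'
#' Each probe first takes its sample's segment mean; those per-probe values
#' are then averaged across all samples of the group. This is the profile
#' copy-number-altered regions are called on.
#'
#' @param profile A `segmentation_profile` (any subset of samples; all rows
#'   are used).
#' @param probe_map The shared probe map.
#' @return A tibble `probe_id`, `chrom`, `pos`, `value`.
#' @export
entity_mean_profile <- function(profile, probe_map) {
  samples <- unique(profile$sample)
  if (length(samples) == 0) stop_bprscan("empty group: no profiles to average")
  acc <- numeric(nrow(probe_map))
  chrom_idx <- split(seq_len(nrow(probe_map)), probe_map$chrom)
  for (s in samples) {
    segs <- profile[profile$sample == s, ]
    for (ch in unique(segs$chrom)) {
      idx <- chrom_idx[[ch]]
      sc <- segs[segs$chrom == ch, ]
      vals <- rep(sc$seg_mean, sc$n_markers)
      if (length(vals) != length(idx)) {
        stop_bprscan("segments of sample ", s, " chromosome ", ch,
                     " do not tile the probe map")
      }
      acc[idx] <- acc[idx] + vals
    }
  }
  dplyr::mutate(as_tibble(probe_map), value = acc / length(samples))
}

#' Call copy-number-altered regions on an entity profile
#'
#' Per chromosome, each probe's deviation from the chromosomal mean is
#' computed; maximal runs of consecutive probes deviating by at least
#' `+threshold` (gain) or at most `-threshold` (loss) become regions.
#'
#' @param entity_profile Tibble from [entity_mean_profile()].
#' @param params A [cna_params()].
#' @return A tibble of regions: `chrom`, `start_pos`, `end_pos`, `n_markers`,
#'   `mean_dev`, `direction` (`"gain"`/`"loss"`).
#' @export
call_altered_regions <- function(entity_profile, params = cna_params()) {
  out <- list()
  for (ch in unique(entity_profile$chrom)) {
    p <- entity_profile[entity_profile$chrom == ch, ]
    dev <- p$value - mean(p$value)
    state <- ifelse(dev >= params$threshold, "gain",
                    ifelse(dev <= -params$threshold, "loss", "neutral"))
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != "neutral" & r$lengths >= params$min_markers_per_region
    if (!any(keep)) next
    out[[ch]] <- tibble(
      chrom = ch,
      start_pos = p$pos[starts[keep]],
      end_pos = p$pos[ends[keep]],
      n_markers = r$lengths[keep],
      mean_dev = vapply(which(keep),
                        function(k) mean(dev[starts[k]:ends[k]]), numeric(1)),
      direction = r$values[keep]
    )
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(0), start_pos = numeric(0),
                  end_pos = numeric(0), n_markers = integer(0),
                  mean_dev = numeric(0), direction = character(0)))
  }
  dplyr::bind_rows(out)
}

#' Altered regions for every group of a cohort
#'
#' Convenience wrapper: averages each group's segmentation profiles and calls
#' regions per group.
#'
#' @param profile A `segmentation_profile` covering all samples.
#' @param groups Tibble `sample`, `group`.
#' @param probe_map The shared probe map.
#' @param params A [cna_params()].
#' @return Region tibble with a leading `group` column.
#' @export
call_group_altered_regions <- function(profile, groups, probe_map,
                                       params = cna_params()) {
  empty <- tibble(group = character(0), chrom = character(0),
                  start_pos = numeric(0), end_pos = numeric(0),
                  n_markers = integer(0), mean_dev = numeric(0),
                  direction = character(0))
  out <- dplyr::bind_rows(lapply(unique(groups$group), function(g) {
    gs <- groups$sample[groups$group == g]
    ep <- entity_mean_profile(profile[profile$sample %in% gs, ], probe_map)
    regs <- call_altered_regions(ep, params)
    if (nrow(regs) > 0) dplyr::mutate(regs, group = g, .before = 1) else NULL
  }))
  if (nrow(out) == 0) empty else out
}
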