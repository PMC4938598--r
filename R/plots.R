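#' Plot a sample's log2 ratios with its fitted segments
#'
#' @param sm Ratio-scale [signal_matrix()].
#' @param profile `segmentation_profile` covering the sample.
#' @param sample Sample id to plot.
#' @param chrom Optional chromosome subset.
#' @return A ggplot object.
#' @export
plot_segments <- function(sm, profile, sample, chrom = NULL) {
  pm <- sm$probe_map
  pts <- dplyr::mutate(as_tibble(pm), value = sm$values[, sample])
  segs <- as_tibble(profile)[profile$sample == sample, ]
  if (!is.null(chrom)) {
    ch <- norm_chrom(chrom)
    pts <- pts[pts$chrom %in% ch, ]
    segs <- segs[segs$chrom %in% ch, ]
  }
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4, colour = "grey40") +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$start_pos, xend = .data$end_pos,
                   y = .data$seg_mean, yend = .data$seg_mean),
      colour = "red", linewidth = 0.8
    ) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "log2 ratio",
                  title = paste("Segmentation:", sample)) +
    ggplot2::theme_minimal()
}

#' Frequency heatmap of a BPR catalog
#'
#' @param object A `bpr_catalog` with frequencies.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bpr_catalog
#' @export
autoplot.bpr_catalog <- function(object, ...) {
  long <- tidy(object)
  long$bpr <- paste0("chr", long$chrom, ":", long$start_pos, "-", long$end_pos)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$bpr,
                                     fill = .data$freq)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "% of samples") +
    ggplot2::labs(x = NULL, y = NULL, title = "BPR occurrence frequencies") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Altered-region map per group
#'
#' Gains and losses as horizontal bars along each chromosome, one row per
#' group.
#'
#' @param regions Tibble from [call_group_altered_regions()].
#' @return A ggplot object.
#' @export
plot_altered_regions <- function(regions) {
  ggplot2::ggplot(regions,
                  ggplot2::aes(x = .data$start_pos, xend = .data$end_pos,
                               y = .data$group, yend = .data$group,
                               colour = .data$direction)) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::scale_colour_manual(values = c(gain = "#2166ac", loss = "#b2182b")) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = "Copy-number-altered regions") +
    ggplot2::theme_minimal()
}
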