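# interval overlap is delegated to IRanges; spans are 1-based inclusive and
# any overlap of >= 1 bp counts

genes_iranges_by_chrom <- function(genes) {
  split(genes, genes$chrom)
}

#' Genes affected by altered regions
#'
#' A gene is affected by a group iff at least one of that group's altered
#' regions overlaps its span by at least 1 bp. Output mirrors a per-gene hit
#' table: one 0/1 flag column per group, total affected-group count and the
#' tumor-associated flag.
#'
#' @param regions Region tibble with columns `group`, `chrom`, `start_pos`,
#'   `end_pos` (e.g. from [call_group_altered_regions()]).
#' @param genes Gene annotation from [read_gene_annotation()].
#' @return A tibble: `gene_id`, `gene_name`, `chrom`, `start`, `end`, one
#'   column per group, `n_groups`, `tumor_associated`. Genes hit by no
#'   region are omitted.
#' @export
affected_genes <- function(regions, genes) {
  groups <- unique(regions$group)
  hits <- matrix(0L, nrow = nrow(genes), ncol = length(groups),
                 dimnames = list(NULL, groups))
  for (ch in intersect(unique(genes$chrom), unique(regions$chrom))) {
    gi <- which(genes$chrom == ch)
    ri <- which(regions$chrom == ch)
    gr <- IRanges::IRanges(genes$start[gi], genes$end[gi])
    rr <- IRanges::IRanges(regions$start_pos[ri], regions$end_pos[ri])
    ov <- IRanges::findOverlaps(gr, rr)
    if (length(ov) == 0) next
    hit_groups <- regions$group[ri[S4Vectors::subjectHits(ov)]]
    hit_genes <- gi[S4Vectors::queryHits(ov)]
    for (g in unique(hit_groups)) {
      hits[unique(hit_genes[hit_groups == g]), g] <- 1L
    }
  }
  keep <- rowSums(hits) > 0
  out <- dplyr::bind_cols(
    genes[keep, c("gene_id", "gene_name", "chrom", "start", "end")],
    as_tibble(hits[keep, , drop = FALSE])
  )
  out$n_groups <- as.integer(rowSums(hits[keep, , drop = FALSE]))
  out$tumor_associated <- genes$tumor_associated[keep]
  out
}

#' Categorize an interval against gene annotation
#'
#' `intragenic` when the interval lies entirely within at least one gene
#' span, `intergenic` when it overlaps no gene, `overlapping` otherwise
#' (straddles at least one gene boundary). The three categories are
#' mutually exclusive and exhaustive.
#'
#' @param chrom,start,end Interval (1-based inclusive). Vectorized.
#' @param genes Gene annotation tibble.
#' @return Character vector in `c("intragenic", "overlapping", "intergenic")`.
#' @export
categorize_interval <- function(chrom, start, end, genes) {
  chrom <- norm_chrom(chrom)
  out <- character(length(chrom))
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    gi <- which(genes$chrom == ch)
    if (length(gi) == 0) { out[qi] <- "intergenic"; next }
    qr <- IRanges::IRanges(start[qi], end[qi])
    gr <- IRanges::IRanges(genes$start[gi], genes$end[gi])
    n_any <- IRanges::countOverlaps(qr, gr)
    n_within <- IRanges::countOverlaps(qr, gr, type = "within")
    out[qi] <- ifelse(n_within > 0, "intragenic",
                      ifelse(n_any > 0, "overlapping", "intergenic"))
  }
  out
}

#' Genomic-context summary of BPRs or altered regions
#'
#' Percentages of intragenic / gene-overlapping / intergenic intervals, per
#' group when a `group` column is present (a BPR catalog counts as a single
#' group `"all"`).
#'
#' @param intervals Tibble with `chrom`, `start_pos`, `end_pos` and
#'   optionally `group`.
#' @param genes Gene annotation tibble.
#' @return A tibble `group`, `category`, `n`, `pct`; percentages per group
#'   sum to 100.
#' @export
location_summary <- function(intervals, genes) {
  if (nrow(intervals) == 0) {
    return(tibble(group = character(0), category = character(0),
                  n = integer(0), pct = numeric(0)))
  }
  grp <- if ("group" %in% names(intervals)) intervals$group else "all"
  cat_lv <- c("intragenic", "overlapping", "intergenic")
  tibble(
    group = grp,
    category = factor(categorize_interval(intervals$chrom,
                                          intervals$start_pos,
                                          intervals$end_pos, genes),
                      levels = cat_lv)
  ) |>
    dplyr::count(.data$group, .data$category, .drop = FALSE) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(category = as.character(.data$category))
}
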