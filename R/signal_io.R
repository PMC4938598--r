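#' Coerce a data frame to a validated probe map
#'
#' A probe map is the coordinate backbone of the pipeline: one row per SNP
#' probe with its autosome and 1-based base-pair position. On ingest the map
#' is restricted to autosomes 1-22, sorted within each chromosome by
#' position, and checked for duplicate coordinates.
#'
#' @param df Data frame with columns `probe_id`, `chrom`, `pos` (a leading
#'   `"chr"` prefix on chromosome labels is stripped).
#' @return A tibble with columns `probe_id`, `chrom` (character `"1"`-`"22"`),
#'   `pos` (double), sorted by chromosome then position.
#' @export
as_probe_map <- function(df) {
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(df))) {
    stop_bprscan("probe map needs columns: ", paste(need, collapse = ", "))
  }
  pm <- tibble(
    probe_id = as.character(df$probe_id),
    chrom = norm_chrom(df$chrom),
    pos = suppressWarnings(as.numeric(df$pos))
  )
  if (anyNA(pm$pos)) {
    bad <- pm$probe_id[is.na(pm$pos)]
    stop_bprscan("non-numeric position for probe(s): ",
                 paste(head(bad, 5), collapse = ", "))
  }
  n0 <- nrow(pm)
  pm <- dplyr::filter(pm, .data$chrom %in% AUTOSOMES)
  dropped <- n0 - nrow(pm)
  if (dropped > 0) {
    message("dropped ", dropped, " non-autosomal probe(s)")
  }
  dup <- duplicated(pm[, c("chrom", "pos")])
  if (any(dup)) {
    d <- pm[dup, ][1, ]
    stop_bprscan("duplicate probe coordinate chr", d$chrom, ":",
                 format(d$pos, scientific = FALSE))
  }
  pm <- pm[order(as.integer(pm$chrom), pm$pos), ]
  class(pm) <- c("probe_map", class(tibble()))
  pm
}

#' Read a probe map from a TSV file
#'
#' Expects a header line with columns `probe_id`, `chrom`, `pos`.
#'
#' @param path Path to a tab-separated file.
#' @return A validated probe-map tibble (see [as_probe_map()]).
#' @export
read_probe_map <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  as_probe_map(df)
}

#' Construct a signal matrix aligned to a probe map
#'
#' A signal matrix holds one value per (probe, sample), either raw summed
#' allele intensities (`scale = "intensity"`, nonnegative) or log2 ratios
#' (`scale = "ratio"`). Rows are reordered to the probe-map order; the scale
#' is carried explicitly so downstream stages can refuse mixed input.
#'
#' @param values Numeric matrix, probes in rows, samples in columns; rownames
#'   are probe ids, colnames sample ids.
#' @param probe_map Probe map the rows align to.
#' @param scale `"intensity"` or `"ratio"`.
#' @return A `signal_matrix` object.
#' @export
signal_matrix <- function(values, probe_map, scale = c("intensity", "ratio")) {
  scale <- match.arg(scale)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_bprscan("signal matrix needs probe-id rownames and sample-id colnames")
  }
  missing_probes <- setdiff(rownames(values), probe_map$probe_id)
  if (length(missing_probes) > 0) {
    stop_bprscan("probe(s) absent from probe map: ",
                 paste(head(missing_probes, 5), collapse = ", "))
  }
  if (scale == "intensity" && any(values < 0, na.rm = TRUE)) {
    stop_bprscan("negative intensities are not allowed on the intensity scale")
  }
  keep <- probe_map$probe_id[probe_map$probe_id %in% rownames(values)]
  if (length(keep) < nrow(probe_map)) {
    stop_bprscan("signal matrix is missing ", nrow(probe_map) - length(keep),
                 " probe(s) present in the probe map")
  }
  values <- values[probe_map$probe_id, , drop = FALSE]
  structure(
    list(values = values, probe_map = probe_map, scale = scale),
    class = "signal_matrix"
  )
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("<signal_matrix> ", nrow(x$values), " probes x ", ncol(x$values),
      " samples, scale: ", x$scale, "\n", sep = "")
  invisible(x)
}

#' Long-format view of a signal matrix
#'
#' @param x A `signal_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `probe_id`, `chrom`, `pos`, `sample`, `value`.
#' @method tidy signal_matrix
#' @export
tidy.signal_matrix <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::bind_cols(x$probe_map, as_tibble(x$values)),
    cols = -c("probe_id", "chrom", "pos"),
    names_to = "sample", values_to = "value"
  )
}

#' Read a per-SNP signal matrix from a TSV file
#'
#' The file's first column must be `probe_id`; remaining columns are one per
#' sample, or one A/B pair per sample when `allele_suffixes` is given, in
#' which case the two allele intensities are summed per probe (the overall
#' SNP intensity is the sum of its two allele intensities).
#'
#' @param path Path to a tab-separated file.
#' @param probe_map Probe map; every probe in the file must be present, and
#'   the matrix is reordered to map order.
#' @param allele_suffixes Optional length-2 character vector, e.g.
#'   `c(".A", ".B")`: columns `<sample><suffix>` are paired and summed.
#' @param scale `"intensity"` (default) or `"ratio"`.
#' @return A `signal_matrix`.
#' @export
read_signal_matrix <- function(path, probe_map, allele_suffixes = NULL,
                               scale = c("intensity", "ratio")) {
  scale <- match.arg(scale)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(df)[1] != "probe_id") {
    stop_bprscan("first column of a signal table must be 'probe_id'")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df$probe_id)
  if (!is.null(allele_suffixes)) {
    stopifnot(length(allele_suffixes) == 2)
    a_cols <- grep(paste0(gsub("([.|()\\^{}+$*?\\[\\]])", "\\\\\\1",
                               allele_suffixes[1]), "$"), colnames(m), value = TRUE)
    samples <- sub(paste0(gsub("([.|()\\^{}+$*?\\[\\]])", "\\\\\\1",
                               allele_suffixes[1]), "$"), "", a_cols)
    b_cols <- paste0(samples, allele_suffixes[2])
    if (!all(b_cols %in% colnames(m))) {
      stop_bprscan("missing B-allele column(s): ",
                   paste(setdiff(b_cols, colnames(m)), collapse = ", "))
    }
    m <- m[, a_cols, drop = FALSE] + m[, b_cols, drop = FALSE]
    colnames(m) <- samples
  }
  signal_matrix(m, probe_map, scale = scale)
}

#' Read gene annotation from GFF3 or BED
#'
#' GFF3 input is restricted to `gene`-typed features; BED intervals are
#' converted from 0-based half-open to the internal 1-based inclusive
#' convention (both via `rtracklayer`). Non-autosomal records are dropped
#' with a logged count. An optional plain-text list of gene ids (one per
#' line) sets the `tumor_associated` flag.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @param format `"gff3"` or `"bed"`; inferred from the extension by default.
#' @param tumor_gene_list Optional path to a one-id-per-line text file.
#' @return A tibble with columns `gene_id`, `gene_name`, `chrom`, `start`,
#'   `end`, `tumor_associated`.
#' @export
read_gene_annotation <- function(path, format = NULL, tumor_gene_list = NULL) {
  format <- tolower(format %||% tools::file_ext(path))
  if (format == "gff") format <- "gff3"
  if (!format %in% c("gff3", "bed")) {
    stop_bprscan("unsupported annotation format: ", format)
  }
  gr <- rtracklayer::import(path, format = format)
  md <- S4Vectors::mcols(gr)
  if (format == "gff3") {
    if ("type" %in% names(md)) gr <- gr[as.character(gr$type) == "gene"]
    md <- S4Vectors::mcols(gr)
    gene_id <- as.character(md$ID %||% md$gene_id %||% md$Name)
    gene_name <- as.character(md$Name %||% gene_id)
  } else {
    gene_id <- as.character(md$name %||% seq_along(gr))
    gene_name <- gene_id
  }
  genes <- tibble(
    gene_id = gene_id,
    gene_name = gene_name,
    chrom = norm_chrom(GenomicRanges::seqnames(gr)),
    start = as.numeric(GenomicRanges::start(gr)),
    end = as.numeric(GenomicRanges::end(gr))
  )
  n0 <- nrow(genes)
  genes <- dplyr::filter(genes, .data$chrom %in% AUTOSOMES)
  if (nrow(genes) < n0) {
    message("dropped ", n0 - nrow(genes), " non-autosomal gene record(s)")
  }
  tumor_ids <- character(0)
  if (!is.null(tumor_gene_list)) {
    tumor_ids <- readr::read_lines(tumor_gene_list)
    tumor_ids <- trimws(tumor_ids[nzchar(trimws(tumor_ids))])
  }
  genes$tumor_associated <- genes$gene_id %in% tumor_ids
  genes[chrom_order(genes$chrom), ]
}

bed_from_intervals <- function(df, name, score = 0L) {
  tibble(
    chrom = paste0("chr", df$chrom),
    start = df$start_pos - 1,
    end = df$end_pos,
    name = name,
    score = score
  )
}

write_bed <- function(bed, path) {
  readr::write_tsv(bed, path, col_names = FALSE)
}

#' Write pipeline result tables to a directory
#'
#' Segments and altered regions are exported both as TSV (1-based inclusive
#' coordinates) and BED (0-based half-open); the BPR catalog is exported as a
#' TSV with per-group counts and percent frequencies, cancer totals, class
#' and NOF flag, plus a BED of the BPR intervals scored by total carrier
#' count. Written TSVs read back identically with [readr::read_tsv()].
#'
#' @param results Named list with any of `segments`, `altered_regions`,
#'   `bpr_catalog`, `hotspots`, `gene_hits` (tibbles as produced by the
#'   pipeline stages).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
write_result_tables <- function(results, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2) != 0) {
    stop_bprscan("cannot write to directory: ", out_dir)
  }
  written <- character(0)
  emit_tsv <- function(df, file) {
    p <- file.path(out_dir, file)
    readr::write_tsv(df, p)
    written <<- c(written, p)
  }
  if (!is.null(results$segments)) {
    emit_tsv(results$segments, "segments.tsv")
    seg <- results$segments
    bed <- bed_from_intervals(seg, name = paste0(seg$sample, "_seg"),
                              score = round(100 * seg$seg_mean))
    write_bed(bed, file.path(out_dir, "segments.bed"))
    written <- c(written, file.path(out_dir, "segments.bed"))
  }
  if (!is.null(results$altered_regions)) {
    emit_tsv(results$altered_regions, "altered_regions.tsv")
    ar <- results$altered_regions
    bed <- bed_from_intervals(ar, name = paste0(ar$group, "_", ar$direction),
                              score = round(100 * abs(ar$mean_dev)))
    write_bed(bed, file.path(out_dir, "altered_regions.bed"))
    written <- c(written, file.path(out_dir, "altered_regions.bed"))
  }
  if (!is.null(results$bpr_catalog)) {
    emit_tsv(results$bpr_catalog, "bpr_catalog.tsv")
    cat_df <- results$bpr_catalog
    score <- if ("cancer_total" %in% names(cat_df)) cat_df$cancer_total else 0L
    bed <- bed_from_intervals(cat_df, name = paste0("BPR_", seq_len(nrow(cat_df))),
                              score = score)
    write_bed(bed, file.path(out_dir, "bpr_catalog.bed"))
    written <- c(written, file.path(out_dir, "bpr_catalog.bed"))
  }
  if (!is.null(results$hotspots)) emit_tsv(results$hotspots, "hotspots.tsv")
  if (!is.null(results$gene_hits)) emit_tsv(results$gene_hits, "gene_hits.tsv")
  invisible(written)
}
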