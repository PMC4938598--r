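#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_pipeline()]: input paths (`probe_map`,
#' `signals`, optional `reference`, `genes`, `tumor_gene_list`, `groups`),
#' `signal_scale` (`"intensity"` or `"ratio"`), `normal_group`, `out_dir`,
#' `seed`, and parameter blocks `segmentation`, `cna`, `bpr` whose entries
#' override the defaults of [segmentation_params()], [cna_params()] and
#' [bpr_params()]. Referenced paths are checked at read time.
#'
#' @param path YAML file path.
#' @return A named list ready for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("probe_map", "signals", "reference", "genes",
                "tumor_gene_list", "groups")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop_bprscan("configured path for '", key, "' does not exist: ", cfg[[key]])
    }
  }
  cfg
}

resolve_params <- function(defaults, overrides, seed = NULL) {
  if (!is.null(overrides)) defaults[names(overrides)] <- overrides
  if (!is.null(seed) && "seed" %in% names(defaults)) defaults$seed <- seed
  defaults
}

#' Run the full CNV/BPR pipeline
#'
#' Stages, in order: reference building and log2-ratio computation (skipped
#' for ratio-scale input), per-sample outlier smoothing and CBS
#' segmentation, per-sample BPR detection, cross-cohort aggregation,
#' frequency computation, four-class recurrency classification, NOF
#' flagging and hotspot clustering; entity-level averaging and
#' copy-number-altered region calling; gene colocalization when an
#' annotation is supplied. Identical configuration and seed give identical
#' results.
#'
#' @param config Named list (or path to a YAML read by
#'   [read_pipeline_config()]). Recognized elements: `probe_map` (path or
#'   tibble), `signals` (path or [signal_matrix()]), `signal_scale`,
#'   `allele_suffixes`, `reference` (path to a reference TSV with a
#'   `ref_mean` column, or a tibble; required for intensity input),
#'   `groups` (path to a TSV `sample  group`, or a tibble), `normal_group`
#'   (default `"normal"`), `genes` (path or tibble), `tumor_gene_list`
#'   (path), `out_dir` (optional: results are also written to disk),
#'   `seed`, and parameter blocks `segmentation`, `cna`, `bpr`.
#' @return A `bpr_pipeline` list: `segments`, `bpr_catalog`, `hotspots`,
#'   `altered_regions`, `gene_hits`, `location`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_pipeline_config(config)
  }
  seed <- as.integer(config$seed %||% 1L)
  seg_par <- do.call(segmentation_params,
                     resolve_params(list(), config$segmentation, seed = NULL))
  seg_par$seed <- seed
  cna_par <- do.call(cna_params, resolve_params(list(), config$cna))
  bpr_par <- do.call(bpr_params, resolve_params(list(), config$bpr))

  pm <- config$probe_map
  if (is.character(pm)) pm <- read_probe_map(pm)

  groups <- config$groups
  if (is.character(groups)) {
    groups <- readr::read_tsv(groups, show_col_types = FALSE)
  }
  groups <- as_tibble(groups)[, c("sample", "group")]

  sm <- config$signals
  if (is.character(sm)) {
    sm <- read_signal_matrix(sm, pm, allele_suffixes = config$allele_suffixes,
                             scale = config$signal_scale %||% "intensity")
  }
  stopifnot(inherits(sm, "signal_matrix"))

  # validate before any compute: every sample needs exactly one group
  missing_grp <- setdiff(colnames(sm$values), groups$sample)
  if (length(missing_grp) > 0) {
    stop_bprscan("no group assignment for sample(s): ",
                 paste(head(missing_grp, 5), collapse = ", "))
  }
  if (anyDuplicated(groups$sample)) {
    stop_bprscan("duplicate group assignment for sample(s): ",
                 paste(groups$sample[duplicated(groups$sample)][1]))
  }
  groups <- groups[groups$sample %in% colnames(sm$values), ]
  normal_group <- config$normal_group %||% "normal"
  group_sizes <- setNames(as.integer(table(groups$group)[unique(groups$group)]),
                          unique(groups$group))
  if (!normal_group %in% names(group_sizes)) {
    stop_bprscan("normal group '", normal_group, "' has no samples")
  }

  ratio_source <- "input"
  if (sm$scale == "intensity") {
    ref <- config$reference
    if (is.null(ref)) {
      stop_bprscan("intensity-scale input requires a reference profile")
    }
    if (is.character(ref)) {
      ref <- readr::read_tsv(ref, show_col_types = FALSE)
    }
    sm <- compute_log2_ratio(sm, ref)
    ratio_source <- "computed"
  }

  segments <- segment_profile(sm, seg_par)
  sample_bprs <- detect_bprs(segments, bpr_par)
  catalog <- aggregate_catalog(sample_bprs, groups, group_sizes,
                               normal_group = normal_group) |>
    frequency_table() |>
    classify_catalog(bpr_par)
  hotspots <- find_hotspots(catalog, bpr_par)
  altered <- call_group_altered_regions(segments, groups, pm, cna_par)

  genes <- config$genes
  gene_hits <- NULL
  location <- NULL
  if (!is.null(genes)) {
    if (is.character(genes)) {
      genes <- read_gene_annotation(genes, tumor_gene_list = config$tumor_gene_list)
    }
    gene_hits <- affected_genes(altered, genes)
    location <- location_summary(
      dplyr::transmute(as_tibble(catalog), group = "bpr_catalog",
                       .data$chrom, .data$start_pos, .data$end_pos), genes)
  }

  manifest <- list(
    seed = seed,
    n_samples = ncol(sm$values),
    n_probes = nrow(sm$values),
    group_sizes = as.list(group_sizes),
    normal_group = normal_group,
    ratio_source = ratio_source,
    segmentation = unclass(seg_par),
    cna = unclass(cna_par),
    bpr = unclass(bpr_par),
    config_hash = rlang::hash(list(unclass(seg_par), unclass(cna_par),
                                   unclass(bpr_par), group_sizes, seed)),
    package_version = as.character(utils::packageVersion("bprscan"))
  )

  res <- structure(
    list(segments = segments, bpr_catalog = catalog, hotspots = hotspots,
         altered_regions = altered, gene_hits = gene_hits,
         location = location, manifest = manifest),
    class = "bpr_pipeline"
  )
  if (!is.null(config$out_dir)) {
    write_result_tables(
      list(segments = as_tibble(segments),
           altered_regions = altered,
           bpr_catalog = round_frequencies(as_tibble(catalog)),
           hotspots = hotspots, gene_hits = gene_hits),
      config$out_dir)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.bpr_pipeline <- function(x, ...) {
  cat("<bpr_pipeline>\n",
      "  samples:   ", x$manifest$n_samples, "\n",
      "  segments:  ", nrow(x$segments), "\n",
      "  BPRs:      ", nrow(x$bpr_catalog), "\n",
      "  hotspots:  ", nrow(x$hotspots), "\n",
      "  CNA regions:", nrow(x$altered_regions), "\n", sep = "")
  invisible(x)
}

#' @method glance bpr_pipeline
#' @export
glance.bpr_pipeline <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_samples = x$manifest$n_samples,
           n_segments = nrow(x$segments),
           n_altered_regions = nrow(x$altered_regions),
           n_hotspots = nrow(x$hotspots)),
    glance(x$bpr_catalog)
  )
}
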