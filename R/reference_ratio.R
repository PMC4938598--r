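#' Build a pooled reference profile from control samples
#'
#' The reference at each probe is the arithmetic mean of the summed allele
#' intensities across all reference samples, on the intensity scale.
#'
#' @param sm An intensity-scale [signal_matrix()] of reference samples.
#' @return A tibble with `probe_id`, `chrom`, `pos`, `ref_mean` and an
#'   attribute `n_reference_samples`.
#' @export
build_reference <- function(sm) {
  stopifnot(inherits(sm, "signal_matrix"))
  if (sm$scale != "intensity") {
    stop_bprscan("reference must be built from intensity-scale signals")
  }
  if (ncol(sm$values) < 1) stop_bprscan("need at least one reference sample")
  mu <- rowMeans(sm$values)
  if (any(mu <= 0)) {
    bad <- rownames(sm$values)[mu <= 0][1]
    stop_bprscan("nonpositive reference mean at probe ", bad)
  }
  out <- dplyr::mutate(sm$probe_map, ref_mean = unname(mu))
  attr(out, "n_reference_samples") <- ncol(sm$values)
  out
}

#' Per-probe log2 ratios of samples against a reference profile
#'
#' `value = log2(sample intensity / reference mean)` at every probe: 0 is
#' copy-neutral, +1/-1 is roughly one copy gained/lost.
#'
#' @param sm An intensity-scale [signal_matrix()] of test samples, aligned to
#'   the same probe map as the reference.
#' @param reference Reference profile from [build_reference()].
#' @return A ratio-scale [signal_matrix()].
#' @export
compute_log2_ratio <- function(sm, reference) {
  stopifnot(inherits(sm, "signal_matrix"))
  if (sm$scale != "intensity") {
    stop_bprscan("log2 ratios are computed from intensity-scale signals")
  }
  if (!identical(rownames(sm$values), reference$probe_id)) {
    stop_bprscan("sample matrix and reference are not aligned to one probe map")
  }
  if (any(sm$values <= 0)) {
    bad <- which(sm$values <= 0, arr.ind = TRUE)[1, ]
    stop_bprscan("nonpositive intensity at probe ",
                 rownames(sm$values)[bad[1]], ", sample ",
                 colnames(sm$values)[bad[2]])
  }
  ratios <- log2(sm$values / reference$ref_mean)
  signal_matrix(ratios, sm$probe_map, scale = "ratio")
}

#' Write a reference profile to TSV
#' @param reference Tibble from [build_reference()].
#' @param path Output path.
#' @export
write_reference <- function(reference, path) {
  readr::write_tsv(reference, path)
}
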