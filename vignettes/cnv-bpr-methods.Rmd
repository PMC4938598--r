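---
title: "Methods: copy-number segmentation and recurrent breakpoint-region analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number segmentation and recurrent breakpoint-region analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bprscan` implements a cohort-scale pipeline for copy-number variation (CNV)
and breakpoint-region (BPR) analysis of SNP-array data: per-probe log2
ratios against a pooled reference, circular binary segmentation (CBS) of
each sample's autosomes, entity-level calling of copy-number-altered
regions, detection of breakpoint regions where adjacent segment means jump,
aggregation of those regions across multi-entity cohorts into a frequency
catalog with a four-class recurrency scheme, and colocalization with gene
annotation. This vignette records the model, the tunable parameters, and
the design choices made where the construction was genuinely open.

## Signal model

The pipeline starts from per-SNP signal intensities (one value per probe
and sample, after allele summation) or directly from log2 ratios. With a
pooled reference — the per-probe arithmetic mean intensity across all
reference samples, computed on the intensity scale — the per-probe ratio is

$$r_i = \log_2\left(\frac{x_i}{\bar{x}^{\mathrm{ref}}_i}\right),$$

so 0 is copy-neutral and ±1 corresponds to roughly one copy gained or lost.
The reference is a plain mean: no trimming, median, or GC/wave correction
is applied. Averaging happens on the intensity scale before the log
transform; the two orders differ by Jensen-type bias, and the intensity
order is the one implemented. Ratio-scale input (for example from the
bundled simulator) bypasses the reference stage; the run manifest records
which path produced the ratios.

Analysis is restricted to autosomes 1–22. Non-autosomal probes, genes and
regions are dropped on ingest with a logged count. Internal coordinates are
1-based inclusive; BED export converts to 0-based half-open.

## Segmentation

Each sample × chromosome track is segmented with a from-scratch CBS
implementation. The split statistic for a circular arc of $k$ markers
against its complement of $n-k$ markers is the pooled-variance two-sample
t-form

$$Z = \frac{\bar{x}_{\mathrm{arc}} - \bar{x}_{\mathrm{comp}}}
          {s\sqrt{1/k + 1/(n-k)}},$$

maximized in absolute value over all arcs with at least `min_width` markers
on both sides of the split. The reference distribution of $T = \max |Z|$ is
obtained by permutation, not by the hybrid tail approximations some
implementations use: exactness and testability were preferred over speed at
the problem sizes this package targets.

Two permutation modes are used:

* **Exact enumeration** when $n! \le$ `n_perm`: all $n!$ orderings are
  evaluated and $p = \#\{T^{(b)} \ge T_{\mathrm{obs}}\}/n!$. This makes the
  p-value for very short stretches a deterministic, exactly testable
  quantity.
* **Monte-Carlo** otherwise: `n_perm` uniform permutations with the add-one
  convention $p = (1 + \#\{T^{(b)} \ge T_{\mathrm{obs}}\})/(1 + n_\mathrm{perm})$,
  early-exiting as soon as the exceedance count already forces
  $p > \alpha$. At the defaults ($\alpha = 0.001$, `n_perm` = 10,000) a
  null stretch typically stops after a handful of permutations, while an
  accepted split always runs the full budget.

A stretch with $p \le \alpha$ is cut at the accepted arc boundaries — two
change-points for an interior arc, one for an arc touching an end — and
the pieces are re-tested recursively; recursion stops when a piece has
fewer than `2 * min_width` markers. When the best arc would strand a flank
shorter than `min_width` at either end of the stretch, that change-point is
dropped and the flank absorbed into the arc. The arc *candidate set* itself
constrains only the arc and its complement (the natural circular reading),
so without this rule a 1–3-marker segment could be emitted; with it, every
reported segment has at least `min_width` markers unless the whole
chromosome is shorter, which is the property users expect from the
`min.width` parameter.

**Noise estimation.** The per-track noise sd is estimated as
`median(|diff(x)|) / (0.6745 * sqrt(2))` — the MAD of lag-1 differences,
robust to true change-points because only the few differences straddling a
boundary are inflated. The estimate is floored at 1e-8 so that noise-free
(exactly piecewise-constant) inputs remain usable: the same floor is
applied to the pooled sd inside the statistic, so a clean step yields a
very large but finite $T$.

**Outlier smoothing.** Before segmentation, a marker whose distance to the
nearest neighboring value within ±`smooth_region` (default 10) markers
exceeds `outlier_sd` (default 4) noise-sd units is moved to that nearest
neighbor value plus `shrink_sd` (default 2) sd toward its original value.
Decisions use the original values, so two adjacent equal spikes — a genuine
short level — are both retained.

**sd-undo pruning.** After recursion, the change-point with the smallest
adjacent mean gap (in noise-sd units) below `undo_sd` (default 0.5) is
removed, the merged mean recomputed from the marker values, and the scan
repeated; the output therefore guarantees all adjacent gaps
≥ `undo_sd * noise_sd`, and pruning never increases the segment count.

**Determinism and tie-breaking.** Every permutation test derives its seed
from the global seed, the stretch coordinates, and a per-sample/chromosome
salt, so results are identical regardless of the order in which samples are
processed, and a whole run is reproducible from one seed. Among arcs whose
statistics tie within a relative 1e-9 (notably an arc and its complement,
which are mathematically equal but accumulate floating-point rounding
differently), the first in lexicographic (start, end) order wins — the same
rule the brute-force oracle in the test suite applies.

Defaults follow standard SNP-array practice: $\alpha = 0.001$,
`min_width` = 4 markers, `undo_sd` = 0.5. `n_perm` defaults to 10,000; the
test suite uses 1,000, which still resolves $\alpha = 0.001$
($p_{\min} = 1/1001$).

## Copy-number-altered regions

For each entity, every probe first takes its sample's segment mean, and
those values are averaged across the entity's samples. Per chromosome, the
deviation of each probe from the chromosomal mean of this averaged profile
is computed, and maximal runs of consecutive probes with deviation
≥ +0.1 (gain) or ≤ −0.1 (loss) become altered regions (both cuts
inclusive). The run construction is the only definition that is
well-formed on a cross-sample average, which has no single segmentation;
where an original segment passes the cut wholly, the two coincide.
`min_markers_per_region` (default 1) optionally drops very short runs.
Mean-centering makes the calls invariant to adding a constant to a whole
chromosome.

## Breakpoint regions and recurrency classes

A breakpoint region is the genomic stretch between the last probe of one
segment and the first probe of the next when the two segment means differ
by strictly more than 0.6 log2 units (about one copy). The true breakpoint
lies somewhere inside; the array layout bounds how precisely it can be
located.

BPRs are matched across samples by exact (chromosome, start, end) identity.
All samples share one array layout, so a recurrent breakpoint lands on the
same probe pair in every carrier; per-position counting presupposes exactly
this. Overlap-tolerant matching is deliberately not the default. Each
sample counts at most once per distinct interval.

Percent frequencies are `100 * carriers / group size`, carried unrounded
through classification; rounding (2 decimals, half away from zero) is
display-only, which avoids knife-edge class flips at the 1.00% / 0.50%
cuts. With $k$ the number of tumor entities at frequency ≥ 1%:

| class | rule |
|---|---|
| 1 (entity-specific) | $k = 1$, regardless of the normal frequency |
| 2 (cancer-specific) | $k \ge 2$, $k/n_\mathrm{entities} \ge 0.25$, normal < 0.5% |
| 3 (common) | $k \ge 2$, $k/n_\mathrm{entities} \ge 0.25$, normal ≥ 0.5% |
| 4 (none) | $k = 0$ |

The published scheme words the entity-fraction cut as "more than 25%" for
one class and "≥ 25%" for the other; both are implemented as ≥ 0.25, the
only reading consistent with every row of the published worked-example
table (which assigns class 2 to a BPR occurring in exactly 2 of 8
entities). With more than 8 entities a BPR can have $k \ge 2$ but fall
below the fraction cut; the scheme leaves that cell empty, and the
implementation returns class 4 with a warning. A BPR is flagged NOF
(noticeable occurrence frequency) when any entity *or* the normal group
reaches 10%.

**Hotspots.** The notion of hotspot areas — stretches where BPRs cluster —
is only qualitative in the literature this package draws on. The
implemented definition is: merge BPR intervals whose gaps are ≤ 100 kb into
maximal clusters and report clusters with ≥ 2 distinct BPRs. Both knobs are
exposed in `bpr_params()`.

## Colocalization

Overlap is computed on 1-based inclusive spans via `IRanges`; ≥ 1 bp
counts, with no minimum overlap fraction. A gene is affected by a group if
any of the group's altered regions overlaps its span. An interval is
*intragenic* when contained in at least one gene span, *intergenic* when it
overlaps none, *overlapping* otherwise; the three categories partition any
interval set. Transcript structure is ignored — genes are flattened spans.
Tumor-associated status comes solely from a user-supplied id list; no
cancer-gene catalog is bundled, and any annotation source (GFF3 or BED) can
be used.

## The synthetic cohort generator

`cohort_spec()` / `simulate_cohort()` generate multi-entity cohorts of
log2-ratio profiles: i.i.d. Gaussian probe noise around 0, plus planted
constant segments that are independently present in each sample with a
per-group probability and shift the profile by a configured jump over a
probe span. Every planted segment contributes two recurrent boundaries
(start and end), placed between consecutive probes so the detectable
interval is exactly the flanking probe pair. Planted spans may not touch on
a chromosome, keeping the ground truth unambiguous. The realized truth
(per-sample presence, per-group carrier counts, boundary intervals) is
returned alongside the matrix, and `truth_to_expected_catalog()` converts
it into the catalog the pipeline should recover.

Choices, made once:

* Default group sizes mirror a large published multi-entity study (377,
  189, 340, 291, 1104, 207, 120, 109 tumor samples in eight entities plus
  432 normals), scalable by a factor for fast tests.
* Noise is i.i.d. Gaussian per probe, default sd 0.15 — well below the 0.6
  BPR threshold, in the range typical of array log2 ratios. No model for
  GC waviness, genotyping error, aneuploidy-wide baseline shifts, or the
  empirical BPR size distribution is attempted; passing tests therefore
  demonstrate correctness of the algorithms under the stated signal model,
  not robustness to those real-data artifacts.
* Default layout is compact (4 chromosomes × 2,000 probes at 1 kb spacing)
  so that full pipeline runs stay desk-scale; larger layouts are ordinary
  spec tables.
* Per-group presence-probability vectors make all four recurrency classes
  constructible by design.

The test suite exercises the pipeline at sizes chosen to keep a full run
in minutes while preserving the statistical regime of interest: 500-marker
tracks with three planted jumps of ≥ 4 noise-sd for boundary recovery, and
an end-to-end cohort of 4 entities × 50 samples plus 50 normals on
4 × 300-probe chromosomes with planted class-1/2/3 designs (jump 1.5,
noise sd 0.15). With jumps of that size, boundary misplacement by even one
probe is vanishingly rare, so the recovered catalog is expected to equal
the planted truth exactly.

## Known limitations

* Exact-boundary matching means platform mixtures (different probe
  layouts) cannot be aggregated; intervals must come from one probe map.
* The entity-fraction classes depend on the number of entities; with many
  entities the scheme's uncovered cell (class "none" with $k \ge 2$) grows.
* Permutation testing is the only split criterion; for very long
  chromosomes the O(n²) arc scan per permutation dominates runtime, which
  is the price of avoiding tail approximations.
* The CNA caller operates on entity averages, so sample-level CNA
  genotypes and integer copy numbers are out of scope.
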