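---
title: "Differential transcriptome maps from multi-platform expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential transcriptome maps from multi-platform expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txmapr)
```

## The problem

Public expression repositories hold many small microarray series for the
same biological condition, measured on different platforms with different
probe sets, probe counts and deposited scales (linear intensities or
logarithms). None of the single series has the power to map where in the
genome a condition differs from another; together they do, if the
probe-level values can be placed on one common scale and pooled per gene.

`txmapr` implements that integration and the downstream comparison. One
*pool* is all samples of one condition; its *transcriptome map* is a
genome-ordered table of per-locus pooled expression values. Comparing two
pools yields per-locus ratios, and the genome is scanned for windows
("segments") enriched in extreme loci. The motivating application class
is dosage biology — e.g. megakaryoblastic leukemia with and without a
trisomy-21 background, where a trisomic chromosome is expected to show a
~1.5x median expression ratio against euploid cells — but the machinery
is condition-agnostic.

## The pipeline

1. **Decode** (`read_annotation`, `read_probe_map`, `read_sample_matrix`,
   `decode_probes`). Probe identifiers are resolved to locus symbols via
   a static mapping table; a probe without an available value contributes
   nothing, an unmapped probe (array control) is counted and skipped. A
   locus measured by several probes contributes several *data points* per
   sample.
2. **Normalize** (`normalize_datasets`), per sample and then across
   samples:
   * *linearize*: log2/log10/ln deposits are exponentiated back to the
     linear scale;
   * *replace non-positives*: values ≤ 0 become 95% of the sample's
     minimum positive value, keeping later ratios defined while marking
     "below detection";
   * *intra-sample*: values are expressed as percent of the sample mean
     (every sample then averages exactly 100);
   * *inter-sample*: scaled quantile normalization maps every sample
     onto the pointwise mean of all samples' empirical quantile curves,
     which accommodates platforms of different probe counts.
3. **Pool** (`pool_values`). The locus value in a condition is the
   unweighted mean of all its data points flattened across samples and
   probes; the data-point count and the SD as percent of the mean are
   kept alongside.
4. **Compare** (`compute_differential`, `flag_extremes`). One entry per
   locus present in both pools, ratio = mean_A / mean_B. Loci in the
   highest and lowest 2.5th percentile of the ratio distribution are
   flagged over/under-expressed.
5. **Scan** (`build_windows`, `call_segments`). Fixed 500 kb windows
   sliding by 250 kb; a window with `n` ratio-carrying loci of which `k`
   are flagged (out of `K` flagged among `N` total) gets the
   hypergeometric upper-tail p-value `P[X >= k]`,
   `X ~ Hypergeometric(N, K, n)`. q-values are Benjamini–Hochberg
   corrected across all window-tail tests; a call requires q < 0.05
   *and* at least 3 flagged genes, and overlapping calls with >50%
   shared flagged genes are deduplicated (lowest q wins).
6. **Summarise** (`single_gene_map`, `chromosome_medians`, `top_genes`).
   The single-gene map repeats the scan at 12,500 bp with a one-gene
   minimum and a "prevail" rule (below); chromosome medians track
   dosage; ranked gene lists are restricted to loci with at least 5 data
   points per pool.

`run_compare()` executes 1–6 from a JSON run config and writes the
report bundle (`segments.tsv`, `genes_over/under.tsv`,
`single_genes.tsv`, `chromosomes.tsv`, `differential.tsv`, `run.log`);
`compare_pools()` is the same pipeline on in-memory objects.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `window` | 500,000 | bp | segment width of the genome scan |
| `shift` | 250,000 | bp | window step (50% overlap: interior loci sit in 2 windows) |
| `gene_window` | 12,500 | bp | single-gene scan width, ~¼ of a mean gene length |
| `tail` | 0.025 | fraction | extreme-gene flag threshold per tail |
| `q_threshold` | 0.05 | — | corrected significance cutoff |
| `min_extreme_genes` | 3 | genes | extreme genes a called segment must contain |
| `min_data_points` | 5 | points | support filter for ranked gene lists |
| `nonpositive_factor` | 0.95 | fraction | replacement for values ≤ 0 |
| `quantile_grid_size` | 1001 | probabilities | tabulation grid of the reference quantile curve |

All defaults are echoed into `run.log` on every run.

## Numerical choices

* **Quantile curves.** Each sample's empirical quantile function
  interpolates linearly through `((i-1)/(n-1), x_(i))` (the
  `stats::quantile` type-7 convention); values are positioned by midrank,
  so ties are deterministic. The reference curve is tabulated on the
  union of the equally spaced probability grid and every sample's own
  knot positions: the mean of piecewise-linear curves is itself
  piecewise linear with knots in that union, so evaluation is exact
  rather than grid-approximate. Two identical samples therefore
  normalize to themselves to machine precision, and equal-length samples
  end with identical sorted vectors (classical quantile normalization).
* **Joint normalization.** Quantile normalization runs across all
  samples of both compared pools jointly, so the two pooled maps share
  one scale and ratios are meaningful.
* **Order of steps.** Non-positive substitution precedes the
  percent-of-mean step so the sample mean is computed on positive values
  only and cannot be dragged down by sentinel values.
* **Pooling.** Flattened, unweighted: a 3-probe sample contributes 3
  points where a 1-probe sample contributes 1 — this is what makes
  reported data-point counts exceed sample counts. The SD is the
  population SD (denominator *n*); the choice is immaterial to any call
  and fixed for determinism.
* **Window membership** is by locus start coordinate: a deterministic
  single-point rule that gives exactly two windows per interior locus at
  50% overlap.
* **Ties at the percentile thresholds** are flagged (inclusive
  comparison), which is deterministic and conservative toward flagging.
* **Correction.** BH by default because the test family (thousands of
  overlapping window-tail tests) makes Bonferroni needlessly harsh;
  `map_params(correction = "bonferroni")` switches.
* **Degenerate inputs.** A sample with no positive value, an empty
  comparison (no shared loci) and fewer than 2 samples for quantile
  normalization are hard errors; a window with no ratio-carrying locus
  simply emits no test; a locus with no data points is omitted from the
  pool rather than erroring.

## The "prevail" rule and a structural limitation

In the single-gene scan a significant window may span more than one
locus. The call attaches to the flagged locus only if its pooled value —
in the pool where it is higher — strictly exceeds the corresponding
value of every co-member; otherwise the call is dropped and counted.

A structural consequence of testing gene windows like segments with BH
correction: an *isolated* flagged locus yields `n = 1, k = 1`, hence
`p = K/N ≈ tail` (about 0.025), which can never survive correction
across thousands of window tests. Significant single genes therefore
arise only where two or more flagged loci share a 12.5 kb window — which
is precisely when the prevail rule is needed. Users wanting per-locus
calls regardless should rank loci by ratio (`top_genes`) rather than
rely on single-gene significance.

## What the synthetic generator emulates — and what it does not

`generate_annotation` / `synthetic_truth` / `generate_pools` /
`write_fixture` state a generative world chosen to mirror the structure
of real multi-platform meta-analyses:

* 2–6 platforms covering 60–100% of loci each, 1–3 probes per covered
  locus, so per-pool mapped-locus counts differ;
* per-data-point multiplicative log-normal noise (default sigma 0.2 on
  the natural-log scale, a typical between-array spread after
  normalization) plus per-platform intensity offsets, which the
  normalizer must remove;
* some platforms depositing log2 values, declared in the config;
* MCAR missingness (default 2%) and non-positive junk values (default
  1%, linear platforms only — a log deposit cannot represent them);
* optional effects: a clustered co-regulated segment (fold > 1 on one
  pool), a dosage chromosome (default factor 1.5, the trisomy
  expectation), and sex-biased loci;
* log-normal locus baselines (median 100, sigma 1) shared across pools.

The default demo world (`simulate_fixture`) places the dosage chromosome
at a realistically small fraction of the genome. That matters: the
intra-sample and quantile normalization steps absorb any signal that is
large relative to the whole sample, so a dosage chromosome carrying a
third of all loci would see its apparent ratio shrink well below the
generative 1.5. At realistic gene densities (~5 loci per 500 kb window,
dosage chromosome ≈ 10% of loci) the recovered chromosome median sits
within [1.35, 1.65].

Not emulated: probe-sequence affinity effects, spatial array artifacts,
intensity-dependent (non-MCAR) missingness, batch structure beyond
platform offsets, and correlated biological replicates. A green
parameter-recovery test therefore establishes that the pipeline recovers
effects under multiplicative noise and platform heterogeneity — not that
it is robust to every failure mode of real arrays.

## Limitations

* The scaled-quantile definition is this package's documented stand-in
  for a procedure whose exact original variant is unpublished; any
  monotone inter-sample normalization onto a common reference will give
  closely similar, not identical, maps.
* One locus per probe is required; multi-locus probes must be resolved
  (or dropped) upstream in the mapping table.
* Extreme-gene thresholds are recomputed per comparison, so flags are
  relative to each comparison's ratio distribution, not genome-wide
  constants.
* Strong, broad true signal (many flagged loci on one chromosome)
  partially deflates itself through normalization, as quantified above
  for the dosage world.
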