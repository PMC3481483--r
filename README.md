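# methcapr

Quality control and group-level analysis of MethylCap-seq / MBD-seq
experiments in R.

Enrichment-based methylation sequencing captures methylated DNA fragments
and sequences them as short single-end reads. Before any biology can be
read off such data, two questions must be answered per sample: *did the
capture work* (a failed capture looks like input DNA) and *is the library
complex enough to reproduce*. methcapr is built for cohort studies — tens to
hundreds of lanes across two or more biological groups — and provides:

* **Experimental QC** with a fail-two-metrics exclusion policy over four
  parameters: unique-alignment rate; **saturation** (Pearson correlation of
  binned coverage between two random halves of the library, with a
  resampling projection to double depth); **CpG enrichment**

  enrichment = (CpGs in extended reads / bases in extended reads) /
  (CpGs in genome / genome length)

  which is ~1 for non-captured input and well above the 1.4 exclusion cutoff
  for successful captures; and **CpG coverage (5x)**, the fraction of
  genomic CpGs covered by at least five extended fragments.
* **Binning**: reads deduplicated by (chrom, strand, 5'), extended to
  fragment length, counted into 500-bp bins with any-overlap semantics, and
  scaled to reads per million (rpm); a compact checksummed binary store plus
  text/bedGraph export.
* **Differential methylation** per locus across >= 2 groups: Wilcoxon
  rank-sum (2 groups, exact where enumerable) or Kruskal–Wallis (> 2), with
  Benjamini–Hochberg FDR within each feature class.
* **Global Methylation Indicator (GMI)**: each bin is classed by CpG
  content (boundary-straddling dimers credited to the earlier bin), the
  Methylation Distribution is the mean rpm per class, and the GMI is its
  trapezoidal area under the curve — one scalar per sample, compared across
  groups by Welch t-test.
* **Clustering**: strict mean-rpm/CV locus filters, optional per-locus
  rescaling, Pearson correlation distance, McQuitty (WPGMA) linkage with
  deterministic tie-breaks, multiscale bootstrap support with AU p-values,
  Newick export, and colour tracking of a reference grouping across
  alternative dendrograms.
* **Browser tracks**: bedGraph and a discretized percentile-rank heatmap
  row format (midranked rpm mapped to L colour levels, invariant to rpm
  scale).
* **A seeded simulator** of CpG-island genomes, methylomes, and
  capture-enriched libraries, so the entire workflow is testable with known
  ground truth and no downloads.

Tabular results are tibbles; fitted/report objects support `tidy()`,
`glance()`, and `autoplot()`.

## Worked example

Simulate a two-group cohort (four tumor-like, four normal-like samples; ten
islands hypomethylated in the normal group), run QC, test islands, and
compare GMIs:

```r
library(methcapr)
library(dplyr)

cfg <- sim_config(genome_length = 5e5, n_islands = 25, n_reads = 30000, seed = 42)
cohort <- simulate_cohort(
  cfg,
  groups = list(tumor = list(n = 4),
                normal = list(n = 4, methylation_prob_island = 0.2)),
  n_diff = 10, seed = 42)

idx <- index_cpg_sites(cohort$genome)
readsets <- lapply(cohort$readsets, remove_duplicates)
qc <- compute_qc(readsets, cohort$genome, idx, seed = 1)
qc[, c("sample", "saturation", "cpg_enrichment", "n_failed", "excluded")]
#>   sample    saturation cpg_enrichment n_failed excluded
#> 1 tumor_01       0.963           4.04        0 FALSE
#> 2 tumor_02       0.963           4.08        0 FALSE
#> ...
#> 8 normal_04      0.959           3.39        0 FALSE
```

Every library passes QC: saturations near 0.96 (threshold 0.5) and
enrichments of 3.4–4.1 (threshold 1.4) are what a successful capture looks
like; an input library would sit near enrichment 1 and be excluded together
with its low saturation.

```r
tracks <- lapply(readsets, count_bins, genome = cohort$genome)
groups <- setNames(cohort$manifest$group, cohort$manifest$sample)
fm <- extract_feature_counts(tracks, cohort$islands, groups = groups)
glance(differential_features(fm, alpha = 0.05))
#>   feature_class test     alpha n_loci n_significant min_p_adjusted
#> 1 cpg_island    wilcoxon  0.05     25            21         0.0340
```

21 of 25 islands reach adjusted p <= 0.05: the ten designed hypomethylated
islands show the largest shifts, and because enrichment rpm is relative
(reads lost at hypomethylated loci reappear elsewhere), neighbouring islands
move too — exactly as in real capture data.

```r
cls <- classify_bins(cohort$genome, idx)
compare_gmi(gmi_table(tracks, cls, groups = groups))
#> <mc_gmi_test> Welch t = 10.515, p = 0.000151; means: tumor = 171160.573, normal = 153227.082
```

The group with hypomethylated islands has the lower global methylation
indicator, detected at p = 1.5e-4 with four samples per group.

The pipeline stages (import -> qc -> bin -> features -> diff/gmi/cluster/
tracks) are also drivable from one YAML config via `run_pipeline()`, or from
a shell through the thin wrapper `inst/cli/methcapr.R`; QC-excluded samples
are dropped from every downstream stage automatically.

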